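# Sequencing-library statistics and run parameters.

#' Sequencing-library statistics
#'
#' Container for the fragment-length and read-length distribution of a
#' paired-end sequencing library. All downstream prediction intervals and
#' default filter cutoffs are functions of these four numbers.
#'
#' @param fragment_mean Mean fragment (insert) length in bp; must be > 0.
#' @param fragment_sd Standard deviation of the fragment length in bp (>= 0).
#' @param read_len_mean Mean read length in bp; must be > 0 and <=
#'   `fragment_mean`.
#' @param read_len_sd Standard deviation of the read length in bp (>= 0).
#' @param n_pairs_sampled Number of properly paired read pairs the estimates
#'   were computed from (informational).
#'
#' @return An object of class `library_stats`.
#' @examples
#' library_stats(450, 40, 100, 0)
#' @export
library_stats <- function(fragment_mean, fragment_sd, read_len_mean,
                          read_len_sd, n_pairs_sampled = NA_integer_) {
  x <- list(fragment_mean = as.numeric(fragment_mean),
            fragment_sd = as.numeric(fragment_sd),
            read_len_mean = as.numeric(read_len_mean),
            read_len_sd = as.numeric(read_len_sd),
            n_pairs_sampled = as.integer(n_pairs_sampled))
  validate_library_stats(x)
  structure(x, class = "library_stats")
}

validate_library_stats <- function(x) {
  for (k in c("fragment_mean", "fragment_sd", "read_len_mean",
              "read_len_sd")) {
    if (is.null(x[[k]]) || !is.finite(x[[k]])) {
      stop("library stats: missing or non-numeric value for '", k, "'",
           call. = FALSE)
    }
  }
  if (x$fragment_mean <= 0) stop("library stats: fragment_mean must be > 0",
                                 call. = FALSE)
  if (x$fragment_sd < 0) stop("library stats: fragment_sd must be >= 0",
                              call. = FALSE)
  if (x$read_len_mean <= 0) stop("library stats: read_len_mean must be > 0",
                                 call. = FALSE)
  if (x$read_len_sd < 0) stop("library stats: read_len_sd must be >= 0",
                              call. = FALSE)
  if (x$fragment_mean < x$read_len_mean) {
    stop("library stats: fragment_mean must be >= read_len_mean",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf(
    "library stats: fragment %.1f +/- %.1f bp, read length %.1f +/- %.1f bp (n = %s pairs)\n",
    x$fragment_mean, x$fragment_sd, x$read_len_mean, x$read_len_sd,
    ifelse(is.na(x$n_pairs_sampled), "?", format(x$n_pairs_sampled))))
  invisible(x)
}

#' Run parameters for the insertion caller
#'
#' Global knobs of a calling run. `s_factor` multiplies the fragment-length
#' standard deviation when computing each anchor's predicted insertion
#' interval; `mapq_min` is the minimum mapping quality required of anchor
#' reads; `bin_size` controls the genomic partitioning used to chunk the
#' clustering stage.
#'
#' @param s_factor Non-negative multiplier of the fragment-length sd
#'   (default 2).
#' @param mapq_min Minimum anchor mapping quality (default 15).
#' @param bin_size Genomic bin size in bp for chunked clustering
#'   (default 5e7).
#' @param n_processes Number of worker processes for per-bin clustering.
#' @param coverage Optional user-supplied fold-coverage; when `NULL` it is
#'   estimated from the BAM and rounded to one decimal.
#' @param min_clip Minimum soft-clip length (bp) for a clip boundary to count
#'   as breakpoint evidence (default 5).
#' @param clip_group_tol Clip positions within this many bp are grouped when
#'   electing the breakpoint (default 3).
#' @param core_margin Core reads must span the breakpoint by at least this
#'   many bp on each side (default 5).
#' @param seed Optional integer seed for any stochastic step.
#'
#' @return A list of class `tei_params`.
#' @export
tei_params <- function(s_factor = 2, mapq_min = 15, bin_size = 5e7,
                       n_processes = 1, coverage = NULL, min_clip = 5,
                       clip_group_tol = 3, core_margin = 5, seed = NULL) {
  stopifnot(s_factor >= 0, mapq_min >= 0, bin_size > 0, n_processes >= 1,
            min_clip >= 0, clip_group_tol >= 0, core_margin >= 0)
  if (!is.null(coverage) && coverage <= 0) {
    stop("coverage must be > 0", call. = FALSE)
  }
  structure(list(s_factor = s_factor, mapq_min = mapq_min,
                 bin_size = bin_size, n_processes = n_processes,
                 coverage = coverage, min_clip = min_clip,
                 clip_group_tol = clip_group_tol, core_margin = core_margin,
                 seed = seed),
            class = "tei_params")
}

# estimation ------------------------------------------------------------

#' Estimate library statistics from properly paired reads
#'
#' Computes mean and (population) standard deviation of fragment length and
#' read length over the first `max_pairs` properly paired read pairs.
#' Fragment length is the absolute template length (TLEN) of the leftmost
#' read of each proper pair, i.e. the aligner's outer insert size.
#'
#' @param x Path to a BAM file, or an alignment table as returned by
#'   [read_bam_alignments()].
#' @param max_pairs Maximum number of proper pairs to sample
#'   (default 1e6).
#'
#' @return A [library_stats()] object with `n_pairs_sampled` set to the
#'   number of pairs actually used.
#' @export
estimate_library_stats <- function(x, max_pairs = 1e6) {
  stopifnot(max_pairs >= 1)
  if (is.character(x)) {
    tab <- .scan_proper_pairs(x, max_pairs)
  } else {
    keep <- x$proper & x$tlen > 0
    tab <- data.frame(tlen = x$tlen[keep], qwidth = x$qwidth[keep])
    tab <- utils::head(tab, max_pairs)
  }
  n <- nrow(tab)
  if (n < min(100, max_pairs)) {
    stop("fewer than 100 properly paired reads found; ",
         "library statistics cannot be estimated (provide a config file)",
         call. = FALSE)
  }
  library_stats(fragment_mean = mean(abs(tab$tlen)),
                fragment_sd = pop_sd(abs(tab$tlen)),
                read_len_mean = mean(tab$qwidth),
                read_len_sd = pop_sd(tab$qwidth),
                n_pairs_sampled = n)
}

.scan_proper_pairs <- function(bam, max_pairs) {
  bf <- Rsamtools::BamFile(bam, yieldSize = 500000L)
  open(bf); on.exit(close(bf))
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("isize", "cigar"), flag = flag)
  tl <- integer(0); qw <- integer(0)
  repeat {
    res <- Rsamtools::scanBam(bf, param = param)[[1]]
    if (length(res$isize) == 0L) break
    keep <- !is.na(res$isize) & res$isize > 0
    if (any(keep)) {
      tl <- c(tl, res$isize[keep])
      qw <- c(qw, parse_cigar(res$cigar[keep])$qwidth)
    }
    if (length(tl) >= max_pairs) break
  }
  data.frame(tlen = utils::head(tl, max_pairs),
             qwidth = utils::head(qw, max_pairs))
}

#' Estimate fold-coverage from mapped reads
#'
#' Fold-coverage is defined as total mapped read bases (reference-aligned
#' widths) divided by total reference length. It feeds the default filter
#' cutoffs; a user-supplied coverage always takes precedence.
#'
#' @param x Path to a BAM file or an alignment table.
#' @param reference_lengths Named numeric vector of reference sequence
#'   lengths in bp. Taken from the BAM header when `x` is a path and this is
#'   `NULL`.
#'
#' @return Fold-coverage (numeric scalar; 0 for an empty BAM).
#' @export
estimate_coverage <- function(x, reference_lengths = NULL) {
  if (is.character(x)) {
    if (is.null(reference_lengths)) {
      reference_lengths <- Rsamtools::scanBamHeader(x)[[1]]$targets
    }
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(what = "cigar", flag = flag)
    cig <- Rsamtools::scanBam(x, param = param)[[1]]$cigar
    bases <- sum(as.numeric(parse_cigar(cig)$ref_width))
  } else {
    if (is.null(reference_lengths)) {
      stop("reference_lengths is required for alignment tables",
           call. = FALSE)
    }
    bases <- sum(as.numeric(x$end - x$start))
  }
  total <- sum(as.numeric(reference_lengths))
  if (length(reference_lengths) == 0L || total <= 0) {
    stop("total reference length must be > 0", call. = FALSE)
  }
  bases / total
}

# config round-trip -----------------------------------------------------

.STATS_KEYS <- c("fragment_mean", "fragment_sd", "read_len_mean",
                 "read_len_sd")
.FILTER_KEYS <- c("cluster_size_min", "cluster_size_max", "span_min",
                  "span_max", "interval_len_min", "interval_len_max",
                  "clipped_support_min", "clipped_support_max",
                  "require_consistent_te")

#' Read library statistics (and optional filter cutoffs) from a config file
#'
#' The config format is plain text with one `key=value` per line and `#`
#' comments. Mandatory keys are `fragment_mean`, `fragment_sd`,
#' `read_len_mean`, `read_len_sd`; the eight filter bounds plus
#' `require_consistent_te` are optional and, when all present, yield a
#' [filter_config()].
#'
#' @param path Path to the config file.
#' @return A list with elements `stats` ([library_stats()]) and `filter`
#'   ([filter_config()] or `NULL`).
#' @seealso [write_stats_config()]
#' @export
load_stats_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("config parse error: malformed line '", lines[bad][1], "'",
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  getval <- function(k, mandatory = TRUE) {
    i <- match(k, keys)
    if (is.na(i)) {
      if (mandatory) stop("config parse error: missing key '", k, "'",
                          call. = FALSE)
      return(NULL)
    }
    if (k == "require_consistent_te") {
      v <- toupper(vals[i]) %in% c("TRUE", "1", "YES")
      return(v)
    }
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) stop("config parse error: non-numeric value for key '",
                       k, "'", call. = FALSE)
    v
  }
  stats <- library_stats(getval("fragment_mean"), getval("fragment_sd"),
                         getval("read_len_mean"), getval("read_len_sd"))
  filt <- NULL
  have_filter <- all(setdiff(.FILTER_KEYS, "require_consistent_te") %in% keys)
  if (have_filter) {
    filt <- filter_config(
      cluster_size_min = getval("cluster_size_min"),
      cluster_size_max = getval("cluster_size_max"),
      span_min = getval("span_min"),
      span_max = getval("span_max"),
      interval_len_min = getval("interval_len_min"),
      interval_len_max = getval("interval_len_max"),
      clipped_support_min = getval("clipped_support_min"),
      clipped_support_max = getval("clipped_support_max"),
      require_consistent_te =
        getval("require_consistent_te", mandatory = FALSE) %||% FALSE)
  }
  list(stats = stats, filter = filt)
}

#' Write library statistics and filter cutoffs to a config file
#'
#' Inverse of [load_stats_config()]; numeric values round-trip exactly
#' (written with full precision).
#'
#' @param stats A [library_stats()] object.
#' @param path Output file path.
#' @param filter Optional [filter_config()] to append.
#' @return `path`, invisibly.
#' @export
write_stats_config <- function(stats, path, filter = NULL) {
  validate_library_stats(stats)
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c("# teiscan run configuration",
             paste0(.STATS_KEYS, "=",
                    vapply(.STATS_KEYS, function(k) fmt(stats[[k]]), "")))
  if (!is.null(filter)) {
    lines <- c(lines, "# filter cutoffs (strict inequalities)",
               vapply(.FILTER_KEYS, function(k) {
                 v <- filter[[k]]
                 paste0(k, "=", if (is.logical(v)) tolower(v) else fmt(v))
               }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}
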