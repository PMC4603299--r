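# Main orchestration: BAM + TE annotation -> filtered insertion calls.

#' Call transposable-element insertions from a paired-end BAM
#'
#' Runs the full pipeline: estimate (or load) library statistics, select
#' valid discordant pairs, classify anchors, cluster per strand into
#' isolated maximal-overlap sets, pair forward/reverse clusters, refine
#' breakpoints with soft-clipped reads, estimate zygosity, and filter with
#' library-derived cutoffs.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM, or an alignment
#'   table from [read_bam_alignments()] (in which case `targets` must be
#'   supplied).
#' @param te A `te_index` from [load_te_annotation()], or a GFF3 path.
#' @param stats Optional [library_stats()]; estimated from the BAM when
#'   `NULL`. A config-file path is also accepted (its filter section, if
#'   any, overrides the generated cutoffs).
#' @param params A [tei_params()].
#' @param targets Named reference-length vector; required for alignment
#'   tables, read from the header for BAM input.
#' @param verbose Log progress to the console.
#' @return An object of class `tei_scan`: list with `calls` (a `tei_calls`
#'   data.frame with `filter_status` set), `stats`, `coverage`,
#'   `filter_config` and `params`.
#' @export
tei_scan <- function(bam, te, stats = NULL, params = tei_params(),
                     targets = NULL, verbose = FALSE) {
  if (is.character(te)) te <- load_te_annotation(te)
  filter_from_config <- NULL
  if (is.character(stats)) {
    cfg <- load_stats_config(stats)
    stats <- cfg$stats
    filter_from_config <- cfg$filter
  }
  if (is.character(bam)) {
    tei_log("reading alignments from ", bam, verbose = verbose)
    aln <- read_bam_alignments(bam)
    targets <- attr(aln, "targets")
  } else {
    aln <- bam
    targets <- targets %||% attr(aln, "targets")
    if (is.null(targets)) {
      stop("targets (reference lengths) required for alignment-table input",
           call. = FALSE)
    }
  }
  if (is.null(stats)) {
    stats <- estimate_library_stats(aln)
    tei_log(sprintf("estimated library: fragment %.1f +/- %.1f, read %.1f",
                    stats$fragment_mean, stats$fragment_sd,
                    stats$read_len_mean), verbose = verbose)
  }
  coverage <- params$coverage %||%
    round(estimate_coverage(aln, targets), 1)
  tei_log(sprintf("coverage: %.1fX", coverage), verbose = verbose)

  anchors <- find_anchor_reads(aln, te, stats, params)
  tei_log(nrow(anchors), " anchor reads", verbose = verbose)
  pairs <- .cluster_and_pair(anchors, params)
  tei_log(length(pairs), " cluster pairs", verbose = verbose)
  calls <- .assemble_calls(pairs, aln, params)

  fc <- filter_from_config %||% default_cutoffs(stats, coverage)
  calls <- apply_filter(calls, fc)
  structure(list(calls = calls, stats = stats, coverage = coverage,
                 filter_config = fc, params = params, targets = targets),
            class = "tei_scan")
}

## clustering + pairing over semantic-preserving genomic chunks
.cluster_and_pair <- function(anchors, params) {
  pairs <- list()
  for (chrom in unique(anchors$chrom)) {
    sub <- anchors[anchors$chrom == chrom, , drop = FALSE]
    chunks <- chunk_anchor_indices(sub, params$bin_size)
    worker <- function(idx) {
      ch <- sub[idx, , drop = FALSE]
      fwd <- cluster_anchors(ch[ch$strand == "+", , drop = FALSE], "+")
      rev <- cluster_anchors(ch[ch$strand == "-", , drop = FALSE], "-")
      pair_clusters(fwd, rev)
    }
    res <- if (params$n_processes > 1L) {
      parallel::mclapply(chunks, worker, mc.cores = params$n_processes)
    } else {
      lapply(chunks, worker)
    }
    pairs <- c(pairs, unlist(res, recursive = FALSE))
  }
  pairs
}

.assemble_calls <- function(pairs, aln, params) {
  n <- length(pairs)
  empty <- data.frame(
    chrom = character(0), lo = numeric(0), hi = numeric(0),
    interval_length = numeric(0), breakpoint = numeric(0),
    clipped_support = integer(0), core_reads = integer(0),
    zygosity = numeric(0), te_name = character(0),
    te_family = character(0), consistent_te = logical(0),
    fwd_size = integer(0), rev_size = integer(0), fwd_span = numeric(0),
    rev_span = numeric(0), fwd_reads = character(0),
    rev_reads = character(0), filter_status = character(0))
  if (n == 0L) {
    class(empty) <- c("tei_calls", "data.frame")
    return(empty)
  }
  cp <- clip_positions(aln, params$min_clip)
  cp_by <- split(cp$pos, cp$chrom)
  tol <- params$clip_group_tol
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    pair <- pairs[[k]]
    ivl <- insertion_interval(pair)
    all_pos <- cp_by[[ivl$chrom]]
    pos <- all_pos[all_pos >= ivl$lo - tol & all_pos <= ivl$hi + tol]
    bp <- NA_real_; support <- 0L
    if (length(pos)) {
      grp <- .best_clip_group(pos, tol)
      bp <- grp$breakpoint
      support <- grp$support
    }
    id <- annotate_te_identity(pair)
    met <- compute_metrics(pair, support)
    rows[[k]] <- data.frame(
      chrom = ivl$chrom, lo = ivl$lo, hi = ivl$hi,
      interval_length = met$interval_length, breakpoint = bp,
      clipped_support = support, core_reads = 0L, zygosity = NA_real_,
      te_name = id$name, te_family = id$family,
      consistent_te = id$consistent_te,
      fwd_size = met$fwd_size, rev_size = met$rev_size,
      fwd_span = met$fwd_span, rev_span = met$rev_span,
      fwd_reads = paste(pair$fwd$qnames, collapse = ";"),
      rev_reads = paste(pair$rev$qnames, collapse = ";"),
      filter_status = "raw", stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  ## core reads: one overlap query for all breakpoints
  has_bp <- which(!is.na(calls$breakpoint))
  if (length(has_bp)) {
    m <- params$core_margin
    q <- GenomicRanges::GRanges(
      calls$chrom[has_bp],
      as_iranges0(calls$breakpoint[has_bp] - m,
                  calls$breakpoint[has_bp] + m))
    pr <- which(aln$proper)
    subj <- GenomicRanges::GRanges(aln$chrom[pr],
                                   as_iranges0(aln$start[pr], aln$end[pr]))
    calls$core_reads[has_bp] <-
      GenomicRanges::countOverlaps(q, subj, type = "within")
    calls$zygosity[has_bp] <- ifelse(
      calls$clipped_support[has_bp] + calls$core_reads[has_bp] > 0,
      calls$clipped_support[has_bp] /
        (calls$clipped_support[has_bp] + calls$core_reads[has_bp]),
      NA_real_)
  }
  calls <- calls[order(calls$chrom, calls$lo, calls$hi), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("tei_calls", "data.frame")
  calls
}

#' @export
print.tei_scan <- function(x, ...) {
  cat("TE insertion scan\n")
  print(x$stats)
  cat(sprintf("coverage: %.1fX\n", x$coverage))
  n <- nrow(x$calls)
  np <- sum(x$calls$filter_status == "pass")
  cat(sprintf("calls: %d raw, %d pass filters\n", n, np))
  invisible(x)
}

#' @method summary tei_scan
#' @export
summary.tei_scan <- function(object, ...) {
  print(object)
  st <- table(object$calls$filter_status)
  cat("filter status:\n")
  for (s in names(st)) cat(sprintf("  %-24s %d\n", s, st[[s]]))
  invisible(object)
}

#' Passing calls of a scan
#'
#' @param scan A `tei_scan` object.
#' @return The subset of calls with `filter_status == "pass"`.
#' @export
filtered_calls <- function(scan) {
  scan$calls[scan$calls$filter_status == "pass", , drop = FALSE]
}
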