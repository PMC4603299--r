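# Call output: GFF3 annotation of insertion sites and a flat table of the
# clusters/reads composing each prediction (greppable with *NIX tools).

#' Write insertion calls as GFF3
#'
#' One `TE_insertion` feature per call; start/end are the insertion
#' interval in 1-based inclusive coordinates, the score column is the
#' clipped support, and attributes carry the breakpoint, zygosity, core
#' reads, cluster metrics and filter status. Missing values are rendered as
#' `.`. Output is ordered by (chrom, start).
#'
#' @param calls A `tei_calls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_gff <- function(calls, path) {
  o <- order(calls$chrom, calls$lo, calls$hi)
  calls <- calls[o, , drop = FALSE]
  dot <- function(x, fmt = NULL) {
    out <- ifelse(is.na(x), ".",
                  if (is.null(fmt)) as.character(x) else sprintf(fmt, x))
    out
  }
  if (nrow(calls) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  ## point intervals (interval_length 0) keep a 1 bp feature
  start1 <- calls$lo + 1
  end1 <- pmax(calls$hi, calls$lo + 1)
  attrs <- paste0(
    "ID=tei_", seq_len(nrow(calls)),
    ";Name=", calls$te_name,
    ";te_family=", calls$te_family,
    ";breakpoint=", dot(calls$breakpoint),
    ";zygosity=", dot(calls$zygosity, "%.3f"),
    ";core_reads=", calls$core_reads,
    ";clipped_support=", calls$clipped_support,
    ";fwd_size=", calls$fwd_size, ";rev_size=", calls$rev_size,
    ";fwd_span=", calls$fwd_span, ";rev_span=", calls$rev_span,
    ";interval_length=", calls$interval_length,
    ";consistent_te=", tolower(calls$consistent_te),
    ";filter_status=", calls$filter_status)
  lines <- paste(calls$chrom, "teiscan", "TE_insertion",
                 format(start1, scientific = FALSE, trim = TRUE),
                 format(end1, scientific = FALSE, trim = TRUE),
                 calls$clipped_support, ".", ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read insertion calls back from a teiscan GFF3 file
#'
#' Inverse of [write_calls_gff()] for the columns it writes (supporting
#' read lists live in the table file, not the GFF).
#'
#' @param path GFF3 file written by [write_calls_gff()].
#' @return A `tei_calls` data.frame.
#' @export
read_calls_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  calls <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    lo = GenomicRanges::start(gr) - 1,
    hi = ifelse(num(mc$interval_length) == 0,
                GenomicRanges::start(gr) - 1,
                GenomicRanges::end(gr)),
    interval_length = num(mc$interval_length),
    breakpoint = num(mc$breakpoint),
    clipped_support = as.integer(num(mc$clipped_support)),
    core_reads = as.integer(num(mc$core_reads)),
    zygosity = num(mc$zygosity),
    te_name = as.character(mc$Name),
    te_family = as.character(mc$te_family),
    consistent_te = as.character(mc$consistent_te) == "true",
    fwd_size = as.integer(num(mc$fwd_size)),
    rev_size = as.integer(num(mc$rev_size)),
    fwd_span = num(mc$fwd_span),
    rev_span = num(mc$rev_span),
    filter_status = as.character(mc$filter_status),
    stringsAsFactors = FALSE)
  class(calls) <- c("tei_calls", "data.frame")
  calls
}

#' Write the per-call cluster/read table
#'
#' Tab-separated, one row per call, fixed column set including the
#' semicolon-delimited supporting read names of each cluster; missing
#' values are `.`. Coordinates are 1-based inclusive on output.
#'
#' @param calls A `tei_calls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  o <- order(calls$chrom, calls$lo, calls$hi)
  calls <- calls[o, , drop = FALSE]
  out <- data.frame(
    chrom = calls$chrom,
    start = calls$lo + 1,
    end = pmax(calls$hi, calls$lo + 1),
    breakpoint = ifelse(is.na(calls$breakpoint), ".",
                        as.character(calls$breakpoint)),
    fwd_size = calls$fwd_size, rev_size = calls$rev_size,
    fwd_span = calls$fwd_span, rev_span = calls$rev_span,
    interval_length = calls$interval_length,
    clipped_support = calls$clipped_support,
    core_reads = calls$core_reads,
    zygosity = ifelse(is.na(calls$zygosity), ".",
                      sprintf("%.3f", calls$zygosity)),
    te_name = calls$te_name, te_family = calls$te_family,
    consistent_te = tolower(calls$consistent_te),
    fwd_reads = ifelse(nzchar(calls$fwd_reads %||% ""),
                       calls$fwd_reads, "."),
    rev_reads = ifelse(nzchar(calls$rev_reads %||% ""),
                       calls$rev_reads, "."),
    filter_status = calls$filter_status,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a call table written by [write_call_table()]
#'
#' @param path Table path.
#' @return A `tei_calls` data.frame (internal 0-based coordinates).
#' @export
read_call_table <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  calls <- data.frame(
    chrom = t$chrom,
    lo = as.numeric(t$start) - 1,
    hi = ifelse(num(t$interval_length) == 0, as.numeric(t$start) - 1,
                as.numeric(t$end)),
    interval_length = num(t$interval_length),
    breakpoint = num(t$breakpoint),
    clipped_support = as.integer(num(t$clipped_support)),
    core_reads = as.integer(num(t$core_reads)),
    zygosity = num(t$zygosity),
    te_name = t$te_name, te_family = t$te_family,
    consistent_te = t$consistent_te == "true",
    fwd_size = as.integer(num(t$fwd_size)),
    rev_size = as.integer(num(t$rev_size)),
    fwd_span = num(t$fwd_span), rev_span = num(t$rev_span),
    fwd_reads = ifelse(t$fwd_reads == ".", "", t$fwd_reads),
    rev_reads = ifelse(t$rev_reads == ".", "", t$rev_reads),
    filter_status = t$filter_status,
    stringsAsFactors = FALSE)
  class(calls) <- c("tei_calls", "data.frame")
  calls
}
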