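# TE annotation loading and interval queries.

#' Load a transposable-element annotation from GFF3
#'
#' Reads a GFF3 annotation of TEs in the reference and builds the interval
#' index used to classify mates and to exclude anchors inside annotated
#' TEs. Each feature must carry a unique `Name` attribute of the form
#' `FAMILY_x`; the family is the name with a single trailing `_digits`
#' suffix removed. GFF 1-based closed coordinates are converted to the
#' package-internal 0-based half-open convention.
#'
#' Features lacking a `Name` get a synthesized unique name (with a warning);
#' duplicated names are made unique with a numeric suffix (with a warning).
#'
#' @param gff_path Path to the GFF3 file.
#' @return A data.frame of class `te_index` with columns `chrom`, `start`,
#'   `end`, `strand`, `name`, `family`.
#' @export
load_te_annotation <- function(gff_path) {
  if (!file.exists(gff_path)) {
    stop("annotation file not found: ", gff_path, call. = FALSE)
  }
  gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                 error = function(e) {
                   stop("failed to parse GFF3 annotation: ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (length(gr) == 0L) {
    stop("annotation contains zero features", call. = FALSE)
  }
  name <- as.character(S4Vectors::mcols(gr)$Name %||%
                         rep(NA_character_, length(gr)))
  if (anyNA(name)) {
    warning(sum(is.na(name)), " feature(s) lack a Name attribute; ",
            "synthesized unique names", call. = FALSE)
    name[is.na(name)] <- paste0("TE_", which(is.na(name)))
  }
  family <- sub("_[0-9]+$", "", name)
  if (anyDuplicated(name)) {
    warning("duplicated Name attributes made unique with a suffix",
            call. = FALSE)
    name <- make.unique(name, sep = "_")
  }
  te_index(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = name,
    family = family,
    stringsAsFactors = FALSE))
}

#' Construct a TE index from a data.frame
#'
#' @param df Data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `name`, and optionally `family` (parsed from
#'   `name` when absent).
#' @return The data.frame with class `te_index` prepended.
#' @export
te_index <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand", "name") %in% names(df)))
  if (is.null(df$family)) df$family <- sub("_[0-9]+$", "", df$name)
  if (any(df$start >= df$end)) {
    stop("TE features must satisfy start < end", call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("TE feature names must be unique", call. = FALSE)
  }
  class(df) <- c("te_index", "data.frame")
  df
}

te_granges <- function(te) {
  GenomicRanges::GRanges(te$chrom, as_iranges0(te$start, te$end))
}

## logical: does [start,end) on chrom overlap any annotated TE?
overlaps_te <- function(chrom, start, end, te) {
  if (length(chrom) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, as_iranges0(start, end))
  GenomicRanges::countOverlaps(q, te_granges(te)) > 0L
}

## list of TE names overlapped by each query interval
te_hits_for <- function(chrom, start, end, te) {
  if (length(chrom) == 0L) return(list())
  q <- GenomicRanges::GRanges(chrom, as_iranges0(start, end))
  hits <- GenomicRanges::findOverlaps(q, te_granges(te))
  out <- vector("list", length(q))
  if (length(hits)) {
    sp <- split(te$name[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- sp
  }
  out
}

#' Write a TE annotation to GFF3
#'
#' @param te A `te_index` (or compatible data.frame, 0-based half-open).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_te_annotation <- function(te, path) {
  gr <- te_granges(te)
  GenomicRanges::strand(gr) <- te$strand
  S4Vectors::mcols(gr)$source <- "teiscan"
  S4Vectors::mcols(gr)$type <- "transposable_element"
  S4Vectors::mcols(gr)$Name <- te$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
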