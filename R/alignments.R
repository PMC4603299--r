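# BAM access and the internal alignment-table representation.
#
# An alignment table is a data.frame with one row per primary mapped record:
#   qname, flag, chrom, start, end (0-based half-open), strand, mapq,
#   cigar, qwidth, lclip, rclip, proper, first, mchrom, mstart, tlen, xa
# `xa` holds the raw alternative-hit tag string ("chrom,(+|-)pos,CIGAR,NM;"
# repeated) or NA.

#' Read primary alignments from a BAM file into a table
#'
#' Loads primary, mapped records (secondary and supplementary alignments are
#' skipped) with the fields the insertion caller needs, converting positions
#' to 0-based half-open coordinates and summarising each CIGAR into
#' reference width and soft-clip lengths.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param which Optional `GRanges` restricting the load to a region.
#' @return A data.frame alignment table (see package internals); attribute
#'   `"targets"` carries the named reference-length vector from the header.
#' @export
read_bam_alignments <- function(bam, which = NULL) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize")
  param <- if (is.null(which)) {
    Rsamtools::ScanBamParam(what = what, flag = flag, tag = "XA")
  } else {
    Rsamtools::ScanBamParam(what = what, flag = flag, tag = "XA",
                            which = which)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  res <- if (length(res) == 1L) res[[1]] else {
    nm <- names(res[[1]])
    stats::setNames(lapply(nm, function(f) {
      if (f == "tag") NULL else do.call(c, lapply(res, `[[`, f))
    }), nm)
  }
  cig <- parse_cigar(res$cigar)
  xa <- res$tag$XA
  if (is.null(xa)) xa <- rep(NA_character_, length(res$pos))
  out <- data.frame(
    qname = as.character(res$qname),
    flag = res$flag,
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + cig$ref_width,
    strand = as.character(res$strand),
    mapq = res$mapq,
    cigar = res$cigar,
    qwidth = cig$qwidth,
    lclip = cig$lclip,
    rclip = cig$rclip,
    proper = bitwAnd(res$flag, 2L) > 0L,
    first = bitwAnd(res$flag, 64L) > 0L,
    mchrom = as.character(res$mrnm),
    mstart = ifelse(is.na(res$mpos), NA_integer_, res$mpos - 1L),
    tlen = res$isize,
    xa = xa,
    stringsAsFactors = FALSE)
  attr(out, "targets") <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  out
}

#' Write an alignment table to a coordinate-sorted, indexed BAM
#'
#' Renders the table as SAM and converts it with [Rsamtools::asBam()]
#' (which sorts and indexes). Used by the read simulator; `seq`/`qual`
#' columns are optional and written as `*` when absent.
#'
#' @param aln Alignment table (see [read_bam_alignments()] for columns;
#'   `flag` is recomputed from `strand`, `proper`, `first` and mate fields
#'   when missing).
#' @param targets Named vector of reference sequence lengths (bp).
#' @param prefix Output path prefix; creates `<prefix>.bam` and its index.
#' @return Path to the BAM file.
#' @export
write_bam_alignments <- function(aln, targets, prefix) {
  stopifnot(length(targets) > 0, !is.null(names(targets)))
  flag <- aln$flag
  if (is.null(flag)) {
    flag <- 1L +                                           # paired
      ifelse(aln$proper, 2L, 0L) +
      ifelse(aln$strand == "-", 16L, 0L) +
      ifelse(aln$mstrand == "-", 32L, 0L) +
      ifelse(aln$first, 64L, 128L)
  }
  mchrom <- ifelse(is.na(aln$mchrom), "*",
                   ifelse(aln$mchrom == aln$chrom, "=", aln$mchrom))
  mpos <- as.integer(ifelse(is.na(aln$mstart), 0L, aln$mstart + 1L))
  seq <- aln$seq %||% rep("*", nrow(aln))
  qual <- aln$qual %||% rep("*", nrow(aln))
  opt <- ifelse(is.na(aln$xa), "", paste0("\tXA:Z:", aln$xa))
  lines <- paste0(aln$qname, "\t", as.integer(flag), "\t", aln$chrom, "\t",
                  as.integer(aln$start + 1L), "\t", as.integer(aln$mapq),
                  "\t", aln$cigar, "\t", mchrom, "\t", mpos, "\t",
                  as.integer(aln$tlen), "\t", seq, "\t", qual, opt)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(targets), "\tLN:",
                     format(targets, scientific = FALSE, trim = TRUE)))
  sam <- paste0(prefix, ".sam")
  con <- file(sam, open = "wb")  # binary mode: byte-identical across runs
  writeLines(c(header, lines), con, sep = "\n")
  close(con)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# XA tag ----------------------------------------------------------------

## Parse XA strings into a long table of alternative placements:
## (idx, chrom, start, end, strand) with 0-based half-open coordinates.
parse_xa <- function(xa) {
  has <- which(!is.na(xa) & nzchar(xa))
  if (length(has) == 0L) {
    return(data.frame(idx = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  parts <- strsplit(xa[has], ";", fixed = TRUE)
  idx <- rep(has, lengths(parts))
  entry <- unlist(parts, use.names = FALSE)
  fld <- strsplit(entry, ",", fixed = TRUE)
  ok <- lengths(fld) >= 3L
  idx <- idx[ok]; fld <- fld[ok]
  chrom <- vapply(fld, `[`, "", 1L)
  posf <- vapply(fld, `[`, "", 2L)
  cig <- vapply(fld, `[`, "", 3L)
  strand <- substr(posf, 1L, 1L)
  pos <- as.integer(substring(posf, 2L))
  w <- parse_cigar(cig)$ref_width
  data.frame(idx = idx, chrom = chrom, start = pos - 1L,
             end = pos - 1L + w, strand = strand, stringsAsFactors = FALSE)
}
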