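# Breakpoint refinement from soft-clipped reads, core-read counting and
# zygosity estimation.

## Table of soft-clip boundary positions (reference coordinate of each clip
## with clip length >= min_clip): columns chrom, pos.
clip_positions <- function(aln, min_clip = 5) {
  left <- aln$lclip >= min_clip
  right <- aln$rclip >= min_clip
  data.frame(chrom = c(aln$chrom[left], aln$chrom[right]),
             pos = c(aln$start[left], aln$end[right]),
             stringsAsFactors = FALSE)
}

## Greedy left-to-right grouping of sorted clip positions: a group collects
## all positions within `tol` bp of its first member. Returns the modal
## position and size of the best-supported group (ties on support broken to
## the leftmost group; modal ties to the smallest position).
.best_clip_group <- function(pos, tol = 3) {
  pos <- sort(pos)
  best_pos <- NA_integer_; best_n <- 0L
  i <- 1L
  n <- length(pos)
  while (i <= n) {
    j <- i
    while (j < n && pos[j + 1L] - pos[i] <= tol) j <- j + 1L
    grp <- pos[i:j]
    tab <- table(grp)
    modal <- as.integer(names(tab)[which.max(tab)])
    if ((j - i + 1L) > best_n) {
      best_n <- j - i + 1L
      best_pos <- modal
    }
    i <- j + 1L
  }
  list(breakpoint = best_pos, support = best_n)
}

#' Locate the insertion breakpoint from soft-clipped reads
#'
#' Collects the reference positions at which reads overlapping the
#' insertion interval are soft-clipped (clip length >= `min_clip`), groups
#' nearby positions (within `tol` bp), and reports the modal position of
#' the group with the highest support.
#'
#' @param x Path to an indexed BAM file or an alignment table.
#' @param chrom,lo,hi Insertion interval (0-based half-open). Clip positions
#'   outside `[lo - tol, hi + tol]` are ignored.
#' @param min_clip Minimum soft-clip length in bp (default 5).
#' @param tol Grouping tolerance in bp (default 3).
#' @return List `(breakpoint, support)`, or `NULL` when no clipped read
#'   falls in the interval.
#' @export
find_breakpoint <- function(x, chrom, lo, hi, min_clip = 5, tol = 3) {
  aln <- .fetch_alignments(x, chrom, lo - tol - 1, hi + tol + 1)
  cp <- clip_positions(aln, min_clip)
  pos <- cp$pos[cp$chrom == chrom & cp$pos >= lo - tol & cp$pos <= hi + tol]
  if (length(pos) == 0L) return(NULL)
  .best_clip_group(pos, tol)
}

.fetch_alignments <- function(x, chrom, lo, hi) {
  if (is.character(x)) {
    which <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(max(1, lo), hi + 1))
    read_bam_alignments(x, which = which)
  } else {
    x[x$chrom == chrom & x$start < hi & x$end > lo, , drop = FALSE]
  }
}

#' Count reference-supporting core reads at a breakpoint
#'
#' Core reads are properly paired reads whose alignment spans the
#' breakpoint by at least `margin` bp on each side; they evidence the
#' reference (no-insertion) allele. A read soft-clipped at the breakpoint
#' cannot satisfy the span condition and therefore counts as clipped, not
#' core.
#'
#' @param x Path to an indexed BAM file or an alignment table.
#' @param chrom Chromosome.
#' @param breakpoint Breakpoint position (0-based).
#' @param margin Required overlap on each side in bp (default 5).
#' @return Integer count.
#' @export
count_core_reads <- function(x, chrom, breakpoint, margin = 5) {
  aln <- .fetch_alignments(x, chrom, breakpoint - margin - 1,
                           breakpoint + margin + 1)
  sum(aln$chrom == chrom & aln$proper &
        aln$start <= breakpoint - margin &
        aln$end >= breakpoint + margin)
}

#' Zygosity (variant allele fraction) of an insertion
#'
#' The fraction of insertion-supporting (clipped) reads among all reads
#' informative at the breakpoint: `clipped / (clipped + core)`. A value
#' near 1 indicates a homozygous insertion, near 0.5 a heterozygous one;
#' somatic insertions in a subclonal cell fraction fall below 0.5.
#'
#' @param clipped Number of clipped reads supporting the breakpoint.
#' @param core Number of reference-supporting core reads.
#' @return Fraction in `[0, 1]`, or `NA` when `clipped + core == 0`.
#' @export
zygosity <- function(clipped, core) {
  stopifnot(clipped >= 0, core >= 0)
  if (clipped + core == 0) return(NA_real_)
  clipped / (clipped + core)
}

#' Predicted TE identity of a cluster pair
#'
#' The predicted element is the most frequent TE name among the TE-mate
#' hits of both clusters (ties broken to the lexicographically smallest
#' name). `consistent_te` records whether the forward and reverse clusters
#' agree on at least one element.
#'
#' @param pair A cluster pair from [pair_clusters()].
#' @return List `(name, family, consistent_te)`.
#' @export
annotate_te_identity <- function(pair) {
  f <- pair$fwd$te_names
  r <- pair$rev$te_names
  all_names <- c(f, r)
  tab <- table(all_names)
  top <- sort(names(tab)[tab == max(tab)])[1]
  list(name = top,
       family = sub("_[0-9]+$", "", top),
       consistent_te = length(intersect(unique(f), unique(r))) > 0L)
}
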