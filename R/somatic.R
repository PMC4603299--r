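# Somatic vs germline classification from matched tumor (TD) / normal (ND)
# samples.

#' Tumor calls absent from the normal call set
#'
#' Retains the filtered tumor (TD) calls whose padded insertion interval
#' overlaps no call interval of the unfiltered normal (ND) set. These are
#' the putative somatic insertions that the ND alignments are then asked to
#' confirm or refute.
#'
#' @param td_calls Filtered TD `tei_calls` data.frame.
#' @param nd_calls Raw (unfiltered) ND `tei_calls` data.frame.
#' @param pad Symmetric padding in bp applied to the TD intervals before
#'   the overlap test (default 200).
#' @return The retained subset of `td_calls`.
#' @export
td_unique_calls <- function(td_calls, nd_calls, pad = 200) {
  if (nrow(td_calls) == 0L || nrow(nd_calls) == 0L) return(td_calls)
  q <- GenomicRanges::GRanges(td_calls$chrom,
                              as_iranges0(pmax(0, td_calls$lo - pad),
                                          td_calls$hi + pad))
  s <- GenomicRanges::GRanges(nd_calls$chrom,
                              as_iranges0(nd_calls$lo, pmax(nd_calls$hi,
                                                            nd_calls$lo + 1)))
  keep <- GenomicRanges::countOverlaps(q, s) == 0L
  td_calls[keep, , drop = FALSE]
}

#' Discordant-read fraction and coverage in the normal sample at a locus
#'
#' Extracts the reads within a window centred on the locus from the ND
#' alignments and tallies (i) the fraction of mapped reads that are
#' discordant (not proper-paired and with the mate on another chromosome or
#' more than twice the mean fragment length away) and (ii) the mean
#' fold-coverage of the window.
#'
#' @param x ND BAM path or alignment table.
#' @param chrom,locus Locus (0-based position) to interrogate.
#' @param window Window width in bp (default 200, centred on `locus`).
#' @param stats A [library_stats()] object (for the discordance distance).
#' @return List `(discordant_fraction, mean_coverage, n_reads)`; both are 0
#'   when the window holds no mapped reads.
#' @export
nd_window_stats <- function(x, chrom, locus, window = 200,
                            stats = NULL) {
  stopifnot(window > 0)
  lo <- locus - window / 2
  hi <- locus + window / 2
  aln <- .fetch_alignments(x, chrom, lo, hi)
  aln <- aln[aln$chrom == chrom & aln$start < hi & aln$end > lo, ,
             drop = FALSE]
  n <- nrow(aln)
  if (n == 0L) {
    return(list(discordant_fraction = 0, mean_coverage = 0, n_reads = 0L))
  }
  fm <- if (is.null(stats)) stop("stats required", call. = FALSE) else
    stats$fragment_mean
  disc <- !aln$proper & !is.na(aln$mchrom) &
    (aln$mchrom != aln$chrom | abs(aln$start - aln$mstart) > 2 * fm)
  bases <- sum(pmin(aln$end, hi) - pmax(aln$start, lo))
  list(discordant_fraction = sum(disc) / n,
       mean_coverage = bases / window,
       n_reads = n)
}

#' Classify a tumor-unique call as somatic or false-negative-in-normal
#'
#' A putative somatic call is demoted to a germline false negative when the
#' normal sample shows `discordant_threshold` or more discordant reads at
#' the locus, and to a low-coverage false negative when the normal coverage
#' in the window is below `min_cov`. Only calls at clean, well-covered
#' normal loci are called somatic.
#'
#' @param discordant_fraction,mean_coverage Output of [nd_window_stats()].
#' @param discordant_threshold Fraction cutoff (default 0.02).
#' @param min_cov Minimum ND fold-coverage (default 8).
#' @return One of `"germline_fn"`, `"low_coverage_fn"`, `"somatic"`.
#' @export
classify_somatic <- function(discordant_fraction, mean_coverage,
                             discordant_threshold = 0.02, min_cov = 8) {
  if (discordant_fraction >= discordant_threshold) return("germline_fn")
  if (mean_coverage < min_cov) return("low_coverage_fn")
  "somatic"
}

#' Somatic insertion calling from a matched tumor/normal pair
#'
#' Compares filtered tumor calls with the unfiltered normal call set,
#' interrogates the normal alignments at each tumor-unique locus, and
#' classifies every tumor-unique call as `somatic`, `germline_fn` (the
#' normal sample shows discordant evidence: a false negative of the normal
#' call set) or `low_coverage_fn` (the normal sample cannot be trusted at
#' that locus).
#'
#' @param td_calls Filtered TD `tei_calls` (rows with `filter_status ==
#'   "pass"` are used).
#' @param nd_calls Raw ND `tei_calls`.
#' @param nd Source of ND alignments: BAM path or alignment table.
#' @param stats [library_stats()] of the ND library.
#' @param window ND interrogation window in bp (default 200).
#' @param pad TD/ND call-subtraction padding in bp (default 200).
#' @param discordant_threshold,min_cov See [classify_somatic()].
#' @return A data.frame of class `tei_somatic`: the tumor-unique calls with
#'   `nd_discordant_fraction`, `nd_mean_coverage` and `verdict` columns.
#' @export
tei_somatic <- function(td_calls, nd_calls, nd, stats, window = 200,
                        pad = 200, discordant_threshold = 0.02,
                        min_cov = 8) {
  if (!is.null(td_calls$filter_status)) {
    td_calls <- td_calls[td_calls$filter_status == "pass", , drop = FALSE]
  }
  uniq <- td_unique_calls(td_calls, nd_calls, pad = pad)
  n <- nrow(uniq)
  frac <- numeric(n); cov <- numeric(n)
  if (n > 0L && is.character(nd)) {
    ## one regional load instead of n random accesses
    nd <- read_bam_alignments(nd)
  }
  for (i in seq_len(n)) {
    locus <- if (!is.na(uniq$breakpoint[i])) uniq$breakpoint[i] else
      floor((uniq$lo[i] + uniq$hi[i]) / 2)
    ws <- nd_window_stats(nd, uniq$chrom[i], locus, window = window,
                          stats = stats)
    frac[i] <- ws$discordant_fraction
    cov[i] <- ws$mean_coverage
  }
  uniq$nd_discordant_fraction <- frac
  uniq$nd_mean_coverage <- cov
  uniq$verdict <- vapply(seq_len(n), function(i) {
    classify_somatic(frac[i], cov[i], discordant_threshold, min_cov)
  }, character(1))
  class(uniq) <- c("tei_somatic", "data.frame")
  uniq
}

#' Sweep the discordant-read cutoff of the somatic classifier
#'
#' Re-applies the somatic classification at several discordant-fraction
#' cutoffs and reports, per cutoff, the percentage of calls eliminated
#' (demoted to `germline_fn`) within each truth class. Mirrors the
#' benchmark design that sweeps the cutoff from 1 % to 3 %.
#'
#' @param verdicts A `tei_somatic` data.frame.
#' @param truth_class Character vector aligned with `verdicts` rows, e.g.
#'   `"somatic"` / `"germline"` labels derived from a simulation truth set.
#' @param cutoffs Fractions to sweep (default `c(.01, .015, .02, .025,
#'   .03)`).
#' @param min_cov Minimum ND coverage (as in [classify_somatic()]).
#' @return Data.frame with columns `cutoff`, `class`, `n`,
#'   `pct_eliminated`.
#' @export
somatic_cutoff_sweep <- function(verdicts, truth_class,
                                 cutoffs = c(0.01, 0.015, 0.02, 0.025,
                                             0.03),
                                 min_cov = 8) {
  stopifnot(nrow(verdicts) == length(truth_class))
  do.call(rbind, lapply(cutoffs, function(ct) {
    elim <- verdicts$nd_discordant_fraction >= ct
    do.call(rbind, lapply(unique(truth_class), function(cl) {
      sel <- truth_class == cl
      data.frame(cutoff = ct, class = cl, n = sum(sel),
                 pct_eliminated = 100 * mean(elim[sel]))
    }))
  }))
}
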