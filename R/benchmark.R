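# One-call benchmark harnesses: simulate -> call -> score, for the
# germline and matched tumor/normal designs.

#' Simulate reads from a planting, call insertions, and score them
#'
#' Convenience harness chaining [simulate_aligned_reads()], [tei_scan()]
#' (library statistics estimated from the simulated BAM, filters generated
#' from them) and [score_predictions()] on the filtered calls.
#'
#' @param sim A [make_sim_genome()] genome.
#' @param planting A [plant_insertions()] object.
#' @param coverage Fold-coverage to simulate.
#' @param seed Integer seed for the read simulation.
#' @param pad Scoring padding in bp (default 20).
#' @param cfg Optional [sim_read_config()] overriding everything but
#'   coverage.
#' @param prefix Output prefix (temporary by default).
#' @return List with `scan` (the `tei_scan` result), `score` (on filtered
#'   calls), `score_raw` (on raw calls) and `bam`.
#' @export
sim_call_benchmark <- function(sim, planting, coverage, seed = NULL,
                               pad = 20, cfg = NULL,
                               prefix = tempfile("teibench")) {
  cfg <- cfg %||% sim_read_config(coverage = coverage)
  cfg$coverage <- coverage
  res <- simulate_aligned_reads(planting, sim, cfg, prefix = prefix,
                                seed = seed)
  scan <- tei_scan(res$bam, sim$te_annotation)
  list(scan = scan,
       score = score_predictions(filtered_calls(scan), res$truth,
                                 pad = pad),
       score_raw = score_predictions(scan$calls, res$truth, pad = pad),
       truth = res$truth,
       bam = res$bam)
}

#' Benchmark somatic classification on a matched tumor/normal pair
#'
#' Simulates a matched pair from a tumor-mode planting (the normal sample
#' shares the germline events and lacks the low-cell-fraction allele),
#' calls insertions in both, and classifies tumor-unique calls against the
#' normal alignments. Because a desk-scale normal run at high coverage
#' leaves almost no spontaneous false negatives, `n_withheld` germline
#' calls are withheld from the normal call set before the tumor-normal
#' subtraction, emulating the false-negative regime of a genome-scale run;
#' the classifier still interrogates the real normal alignments.
#'
#' @param sim A [make_sim_genome()] genome.
#' @param planting A tumor-mode [plant_insertions()] object.
#' @param coverage Fold-coverage for both samples (default 40).
#' @param seed Integer seed (tumor reads, normal reads and the withheld
#'   subset derive from it).
#' @param n_withheld Number of germline normal calls to withhold
#'   (default 15).
#' @param window,discordant_threshold,min_cov Passed to [tei_somatic()].
#' @param match_pad Truth-matching padding in bp for labelling verdicts
#'   (default 100).
#' @return List with `verdicts` (a `tei_somatic` table), `labels` (truth
#'   class per verdict: `"somatic"`, `"germline"` or `"fp"`), `sweep`
#'   (the [somatic_cutoff_sweep()] table) and the two `tei_scan` results.
#' @export
benchmark_somatic_pair <- function(sim, planting, coverage = 40,
                                   seed = NULL, n_withheld = 15,
                                   window = 200,
                                   discordant_threshold = 0.02,
                                   min_cov = 8, match_pad = 100) {
  stopifnot(planting$mode == "tumor")
  if (!is.null(seed)) set.seed(seed)
  nd_pl <- as_normal_planting(planting)
  td <- simulate_aligned_reads(planting, sim,
                               sim_read_config(coverage = coverage),
                               prefix = tempfile("td"),
                               seed = if (is.null(seed)) NULL else seed + 1L)
  nd <- simulate_aligned_reads(nd_pl, sim,
                               sim_read_config(coverage = coverage),
                               prefix = tempfile("nd"),
                               seed = if (is.null(seed)) NULL else seed + 2L,
                               keep_alignments = TRUE)
  td_scan <- tei_scan(td$bam, sim$te_annotation)
  nd_scan <- tei_scan(nd$bam, sim$te_annotation)

  ## withhold germline-matched normal calls to create TD-unique germline
  ## contaminants
  nd_calls <- nd_scan$calls
  pos <- ifelse(is.na(nd_calls$breakpoint),
                floor((nd_calls$lo + nd_calls$hi) / 2), nd_calls$breakpoint)
  germ <- nd$truth
  matched <- which(vapply(seq_len(nrow(nd_calls)), function(i) {
    any(germ$chrom == nd_calls$chrom[i] &
          abs(germ$position - pos[i]) <= match_pad)
  }, logical(1)))
  withhold <- if (length(matched) > 0 && n_withheld > 0) {
    sample(matched, min(n_withheld, length(matched)))
  } else integer(0)
  nd_raw <- if (length(withhold)) nd_calls[-withhold, , drop = FALSE] else
    nd_calls

  verdicts <- tei_somatic(filtered_calls(td_scan), nd_raw, nd$alignments,
                          nd_scan$stats, window = window,
                          discordant_threshold = discordant_threshold,
                          min_cov = min_cov)
  tr <- planting$truth
  labels <- vapply(seq_len(nrow(verdicts)), function(i) {
    p <- if (!is.na(verdicts$breakpoint[i])) verdicts$breakpoint[i] else
      floor((verdicts$lo[i] + verdicts$hi[i]) / 2)
    sel <- tr$chrom == verdicts$chrom[i] &
      abs(tr$position - p) <= match_pad
    if (!any(sel)) return("fp")
    if (any(tr$class[sel] == "lcf")) "somatic" else "germline"
  }, character(1))
  sweep <- somatic_cutoff_sweep(
    verdicts, ifelse(labels == "somatic", "somatic", "germline"))
  list(verdicts = verdicts, labels = labels, sweep = sweep,
       td_scan = td_scan, nd_scan = nd_scan, n_withheld = length(withhold))
}
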