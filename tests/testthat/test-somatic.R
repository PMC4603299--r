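# Tumor/normal subtraction, normal-window interrogation, somatic verdicts.

mk_calls <- function(chrom, lo, hi, breakpoint = NA) {
  df <- data.frame(chrom = chrom, lo = lo, hi = hi,
                   interval_length = hi - lo, breakpoint = breakpoint,
                   clipped_support = 5L, core_reads = 5L, zygosity = 0.5,
                   te_name = "A_1", te_family = "A", consistent_te = TRUE,
                   fwd_size = 5L, rev_size = 5L, fwd_span = 50,
                   rev_span = 50, fwd_reads = "r", rev_reads = "r",
                   filter_status = "pass", stringsAsFactors = FALSE)
  class(df) <- c("tei_calls", "data.frame")
  df
}

test_that("tumor-unique selection removes padded overlaps with normal
           calls", {
  td <- mk_calls("chr1", 1000, 1100)
  expect_equal(nrow(td_unique_calls(td, mk_calls("chr1", 1050, 1150))), 0L)
  expect_equal(nrow(td_unique_calls(td, mk_calls("chr1", 5000, 5100))), 1L)
  expect_equal(nrow(td_unique_calls(td, td)), 0L)
  ## padding: ND call 150 bp away still collides at pad 200
  expect_equal(nrow(td_unique_calls(td, mk_calls("chr1", 1250, 1350),
                                    pad = 200)), 0L)
  expect_equal(nrow(td_unique_calls(td, mk_calls("chr1", 1250, 1350),
                                    pad = 10)), 1L)
})

test_that("normal-window statistics tally discordant fraction and
           coverage", {
  stats <- library_stats(450, 40, 100, 0)
  ## 100 reads overlapping the window, 5 with a far-away mate
  rows <- lapply(1:100, function(i) {
    far <- i <= 5
    aln_row(paste0("r", i), start = 980 + i %% 7, width = 100,
            proper = !far, mchrom = "chr1",
            mstart = if (far) 50000L else 1300L)
  })
  aln <- do.call(rbind, rows)
  ws <- nd_window_stats(aln, "chr1", 1050, window = 200, stats = stats)
  expect_equal(ws$discordant_fraction, 0.05)

  ## empty window
  ws0 <- nd_window_stats(aln, "chr1", 500000, window = 200, stats = stats)
  expect_equal(ws0$discordant_fraction, 0)
  expect_equal(ws0$mean_coverage, 0)

  ## 50 reads each contributing 100 bp to a 200 bp window -> 25X
  rows <- lapply(1:50, function(i) {
    aln_row(paste0("s", i), start = 1050, width = 100, proper = TRUE)
  })
  aln <- do.call(rbind, rows)
  ws <- nd_window_stats(aln, "chr1", 1100, window = 200, stats = stats)
  expect_equal(ws$mean_coverage, 25)
})

test_that("verdicts follow the discordant-fraction and coverage rules", {
  expect_equal(classify_somatic(0.05, 30), "germline_fn")
  expect_equal(classify_somatic(0.0, 30), "somatic")
  expect_equal(classify_somatic(0.0, 5), "low_coverage_fn")
  ## threshold boundary: exactly 2 % is a germline FN
  expect_equal(classify_somatic(0.02, 30), "germline_fn")
})

test_that("raising the discordant cutoff never decreases the somatic
           count", {
  set.seed(11)
  frac <- runif(100, 0, 0.06)
  cov <- rep(30, 100)
  counts <- vapply(c(0.01, 0.015, 0.02, 0.025, 0.03), function(ct) {
    sum(vapply(seq_along(frac), function(i) {
      classify_somatic(frac[i], cov[i], discordant_threshold = ct)
    }, "") == "somatic")
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("a normal-equals-tumor comparison yields zero somatic calls", {
  fx <- small_sim()
  scan <- tei_scan(fx$res$alignments, fx$sim$te_annotation,
                   stats = fx$res$stats, targets = fx$res$targets)
  verd <- tei_somatic(filtered_calls(scan), scan$calls,
                      fx$res$alignments, fx$res$stats)
  expect_equal(nrow(verd), 0L)
  expect_equal(sum(verd$verdict == "somatic"), 0L)
})
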