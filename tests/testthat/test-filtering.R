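# Library-derived cutoffs and call filtering.

mk_call <- function(fwd_size = 10L, rev_size = 10L, fwd_span = 50,
                    rev_span = 50, interval_length = 300,
                    clipped_support = 10L, consistent_te = TRUE) {
  df <- data.frame(chrom = "chr1", lo = 1000, hi = 1000 + interval_length,
                   interval_length = interval_length, breakpoint = 1100,
                   clipped_support = clipped_support, core_reads = 5L,
                   zygosity = 0.5, te_name = "A_1", te_family = "A",
                   consistent_te = consistent_te, fwd_size = fwd_size,
                   rev_size = rev_size, fwd_span = fwd_span,
                   rev_span = rev_span, fwd_reads = "r1", rev_reads = "r2",
                   filter_status = "raw", stringsAsFactors = FALSE)
  class(df) <- c("tei_calls", "data.frame")
  df
}

test_that("default cutoffs substitute the library statistics into the
           published bound formulas", {
  fc <- default_cutoffs(library_stats(450, 40, 100, 0), 20)
  expect_equal(fc$cluster_size_min, 2)
  expect_equal(fc$cluster_size_max, 100)
  expect_equal(fc$clipped_support_max, 100)
  expect_equal(fc$span_min, 2)
  expect_equal(fc$span_max, 450)
  expect_equal(fc$interval_len_min, 100)
  expect_equal(fc$interval_len_max, 2 * (450 + 80 - 100))  # 860

  fc2 <- default_cutoffs(library_stats(450, 0, 100, 0), 10)
  expect_equal(fc2$interval_len_max, 700)
  expect_equal(fc2$cluster_size_max, 50)

  expect_error(default_cutoffs(library_stats(450, 40, 100, 0), 0.5),
               "coverage too low")
})

test_that("filtering uses strict bounds and records the first violated
           criterion", {
  fc <- default_cutoffs(library_stats(450, 40, 100, 0), 20)
  expect_equal(apply_filter(mk_call(), fc)$filter_status, "pass")
  expect_equal(apply_filter(mk_call(fwd_size = 2L), fc)$filter_status,
               "fail:cluster_size")
  expect_equal(apply_filter(mk_call(rev_span = 450), fc)$filter_status,
               "fail:span")
  ## value equal to the upper bound fails (strict inequality)
  expect_equal(apply_filter(mk_call(interval_length = 860),
                            fc)$filter_status, "fail:interval_length")
  expect_equal(apply_filter(mk_call(clipped_support = 2L),
                            fc)$filter_status, "fail:clipped_support")
  ## consistent_te only enforced on demand
  expect_equal(apply_filter(mk_call(consistent_te = FALSE),
                            fc)$filter_status, "pass")
  fc$require_consistent_te <- TRUE
  expect_equal(apply_filter(mk_call(consistent_te = FALSE),
                            fc)$filter_status, "fail:consistent_te")
})

test_that("filtering is idempotent and monotone in the bounds", {
  set.seed(5)
  calls <- do.call(rbind, lapply(1:60, function(i) {
    mk_call(fwd_size = sample(1:120, 1), rev_size = sample(1:120, 1),
            fwd_span = sample(0:500, 1), rev_span = sample(0:500, 1),
            interval_length = sample(50:900, 1),
            clipped_support = sample(0:120, 1))
  }))
  fc <- default_cutoffs(library_stats(450, 40, 100, 0), 20)
  once <- apply_filter(calls, fc)
  twice <- apply_filter(once, fc)
  expect_identical(once, twice)

  ## widening any bound never removes a passing call
  wide <- fc
  wide$cluster_size_max <- fc$cluster_size_max * 2
  wide$span_max <- fc$span_max * 2
  wide$interval_len_min <- fc$interval_len_min / 2
  wide$interval_len_max <- fc$interval_len_max * 2
  wide$clipped_support_max <- fc$clipped_support_max * 2
  relaxed <- apply_filter(calls, wide)
  was_pass <- once$filter_status == "pass"
  expect_true(all(relaxed$filter_status[was_pass] == "pass"))
})

test_that("cluster-pair metrics match their definitions", {
  p <- mk_pair(fwd_starts = c(100, 110, 120, 130), rev_ends = c(500, 520))
  m <- compute_metrics(p, clipped_support = 7L)
  expect_equal(m$fwd_size, 4L)
  expect_equal(m$fwd_span, 30)
  expect_equal(m$rev_size, 2L)
  expect_equal(m$interval_length, 500 - 130)
  expect_equal(m$clipped_support, 7L)
  ## stacked reads have span 0
  p0 <- mk_pair(fwd_starts = rep(200, 3), rev_ends = c(500, 500))
  expect_equal(compute_metrics(p0)$fwd_span, 0)
  expect_equal(compute_metrics(p0)$rev_span, 0)
})

test_that("filtered call sets on simulation are never less precise than
           raw ones", {
  fx <- small_sim()
  scan <- tei_scan(fx$res$alignments, fx$sim$te_annotation,
                   stats = fx$res$stats, targets = fx$res$targets)
  raw <- score_predictions(scan$calls, fx$res$truth, pad = 20)
  fil <- score_predictions(filtered_calls(scan), fx$res$truth, pad = 20)
  expect_gte(fil$ppv, raw$ppv)
})
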