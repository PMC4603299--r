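# Library-statistics estimation, coverage, and config round-trips.

proper_pairs_tab <- function(tlens, width = 100) {
  n <- length(tlens)
  out <- data.frame(qname = paste0("p", seq_len(max(n, 1))),
                    chrom = "chr1", start = seq_len(max(n, 1)) * 1000,
                    end = seq_len(max(n, 1)) * 1000 + width,
                    strand = "+", mapq = 37L, qwidth = width, lclip = 0L,
                    rclip = 0L, proper = TRUE, first = TRUE,
                    mchrom = "chr1", mstart = NA,
                    tlen = as.integer(c(tlens, 450L)[seq_len(max(n, 1))]),
                    xa = NA_character_, stringsAsFactors = FALSE)
  out[seq_len(n), , drop = FALSE]
}

test_that("library statistics over proper pairs match direct arithmetic", {
  tab <- proper_pairs_tab(rep(450L, 1000))
  st <- estimate_library_stats(tab)
  expect_equal(st$fragment_mean, 450)
  expect_equal(st$fragment_sd, 0)
  expect_equal(st$read_len_mean, 100)
  expect_equal(st$read_len_sd, 0)
  expect_equal(st$n_pairs_sampled, 1000L)

  ## population sd on an enumerated multiset
  tab2 <- proper_pairs_tab(rep(c(400L, 500L), each = 250))
  st2 <- estimate_library_stats(tab2)
  expect_equal(st2$fragment_mean, 450)
  expect_equal(st2$fragment_sd, 50)
})

test_that("sampling is truncated at max_pairs and order-invariant", {
  tab <- proper_pairs_tab(sample(rep(c(400L, 500L), each = 500)))
  expect_equal(estimate_library_stats(tab, max_pairs = 10)$n_pairs_sampled,
               10L)
  full <- estimate_library_stats(tab)
  perm <- estimate_library_stats(tab[sample.int(nrow(tab)), ])
  expect_equal(perm$fragment_mean, full$fragment_mean)
  expect_equal(perm$fragment_sd, full$fragment_sd)
})

test_that("unusable libraries are rejected", {
  expect_error(estimate_library_stats(proper_pairs_tab(rep(450L, 50))),
               "fewer than 100")
  empty <- proper_pairs_tab(integer(0))
  expect_error(estimate_library_stats(empty), "fewer than 100")
})

test_that("coverage is mapped bases over reference length", {
  tab <- proper_pairs_tab(rep(450L, 1000))   # 1000 reads x 100 bp
  expect_equal(estimate_coverage(tab, c(chr1 = 1e6)), 0.1)
  tab2 <- proper_pairs_tab(rep(450L, 20000))
  expect_equal(estimate_coverage(tab2, c(chr1 = 1e5)), 20)
  expect_equal(estimate_coverage(proper_pairs_tab(integer(0)),
                                 c(chr1 = 1e6)), 0)
  expect_error(estimate_coverage(tab, numeric(0)), "reference length")
})

test_that("config files round-trip exactly and fail loudly", {
  st <- library_stats(450.123456789, 40.25, 100, 0.5)
  fc <- default_cutoffs(st, 20)
  path <- withr::local_tempfile()
  write_stats_config(st, path, filter = fc)
  back <- load_stats_config(path)
  expect_equal(back$stats$fragment_mean, 450.123456789)
  expect_equal(back$stats$read_len_sd, 0.5)
  expect_equal(back$filter$interval_len_max, fc$interval_len_max)
  expect_false(back$filter$require_consistent_te)

  writeLines(c("fragment_mean=450", "read_len_mean=100", "read_len_sd=0"),
             path)
  expect_error(load_stats_config(path), "fragment_sd")
  writeLines(c("fragment_mean=-1", "fragment_sd=40", "read_len_mean=100",
               "read_len_sd=0"), path)
  expect_error(load_stats_config(path), "fragment_mean")
  writeLines(c("fragment_mean=abc", "fragment_sd=40", "read_len_mean=100",
               "read_len_sd=0"), path)
  expect_error(load_stats_config(path), "non-numeric")
})

test_that("stats invariants are enforced at construction", {
  expect_error(library_stats(-1, 40, 100, 0), "fragment_mean")
  expect_error(library_stats(450, -1, 100, 0), "fragment_sd")
  expect_error(library_stats(450, 40, 500, 0), "fragment_mean")
})

test_that("simulated libraries are recovered from the BAM within
           sampling error", {
  fx <- small_sim()
  st <- estimate_library_stats(fx$res$bam)
  n <- st$n_pairs_sampled
  expect_lt(abs(st$fragment_mean - 450), 3 * 40 / sqrt(n) + 1)
  expect_equal(st$read_len_mean, 100)
})
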