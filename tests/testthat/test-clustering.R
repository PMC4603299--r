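# Clustering: maximal-clique sweep, isolation, pairing, insertion
# intervals, binning.

test_that("mutually overlapping intervals form a single cluster with the
           intersection interval", {
  a <- anchor_df(ilo = c(0, 5, 8), ihi = c(10, 15, 20))
  cl <- cluster_anchors(a, "+")
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 3L)
  expect_equal(cl[[1]]$lo, 8)
  expect_equal(cl[[1]]$hi, 10)
})

test_that("disjoint intervals give isolated singleton clusters", {
  a <- anchor_df(ilo = c(0, 100), ihi = c(10, 110))
  cl <- cluster_anchors(a, "+")
  expect_length(cl, 2L)
  expect_equal(sort(vapply(cl, `[[`, 0L, "size")), c(1L, 1L))
})

test_that("conflicting cliques are discarded wholesale", {
  ## cliques {1,2} and {2,3} share anchor 2 -> both discarded
  a <- anchor_df(ilo = c(0, 5, 12), ihi = c(10, 15, 25))
  expect_length(cluster_anchors(a, "+"), 0L)
})

test_that("sweep clustering equals the brute-force maximal-clique oracle", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(1:12, 1)
    lo <- sample(0:60, n, replace = TRUE)
    hi <- lo + sample(1:30, n, replace = TRUE)
    a <- anchor_df(ilo = lo, ihi = hi)
    got <- cluster_sets(cluster_anchors(a, "+"))
    want <- lapply(oracle_clusters(lo, hi), sort)
    want <- want[order(vapply(want, paste, "", collapse = ","))]
    expect_equal(got, want, info = paste("instance", rep))
  }
})

test_that("clustering is invariant to anchor input order", {
  set.seed(7)
  lo <- sample(0:500, 30, replace = TRUE)
  hi <- lo + sample(20:80, 30, replace = TRUE)
  a <- anchor_df(ilo = lo, ihi = hi)
  ref <- cluster_sets(cluster_anchors(a, "+"))
  for (k in 1:5) {
    perm <- sample.int(nrow(a))
    b <- a[perm, , drop = FALSE]
    got <- lapply(cluster_sets(cluster_anchors(b, "+")),
                  function(s) sort(perm[s]))
    got <- got[order(vapply(got, paste, "", collapse = ","))]
    expect_equal(got, ref)
  }
})

test_that("forward and reverse clusters pair by interval overlap, with
           ambiguous constellations dropped", {
  mkcl <- function(lo, hi) {
    lapply(seq_along(lo), function(i) {
      list(chrom = "chr1", idx = i, lo = lo[i], hi = hi[i], size = 3L,
           span = 10, starts = lo[i], ends = hi[i], qnames = "r",
           te_names = "A_1")
    })
  }
  expect_length(pair_clusters(mkcl(100, 300), mkcl(250, 400)), 1L)
  expect_length(pair_clusters(mkcl(100, 200), mkcl(300, 400)), 0L)
  ## F1 overlaps R1 and R2 -> everything dropped
  expect_warning(
    pr <- pair_clusters(mkcl(100, 300), mkcl(c(250, 280), c(400, 500))),
    "ambiguous")
  expect_length(pr, 0L)
})

test_that("the insertion-site interval is innermost-read bounded and
           collapses on crossing stacks", {
  p <- mk_pair(fwd_starts = c(100, 140, 180), rev_ends = c(420, 460))
  iv <- insertion_interval(p)
  expect_equal(c(iv$lo, iv$hi, iv$interval_length), c(180, 420, 240))

  p <- mk_pair(fwd_starts = 100, rev_ends = 400)
  iv <- insertion_interval(p)
  expect_equal(c(iv$lo, iv$hi), c(100, 400))

  p <- mk_pair(fwd_starts = 500, rev_ends = 450)
  iv <- insertion_interval(p)
  expect_equal(iv$lo, 475)
  expect_equal(iv$interval_length, 0L)
})

test_that("chunked clustering reproduces the single-pass call set", {
  fx <- small_sim()
  stats <- fx$res$stats
  aln <- fx$res$alignments
  anc <- teiscan:::find_anchor_reads(aln, fx$sim$te_annotation, stats,
                                     tei_params())
  single <- teiscan:::.cluster_and_pair(anc, tei_params(bin_size = 1e9))
  chunked <- teiscan:::.cluster_and_pair(
    anc, tei_params(bin_size = 10 * stats$fragment_mean))
  key <- function(pairs) {
    sort(vapply(pairs, function(p) {
      paste(p$chrom, min(p$fwd$starts), max(p$rev$ends), p$fwd$size,
            p$rev$size)
    }, ""))
  }
  expect_gt(length(single), 0L)
  expect_equal(key(chunked), key(single))
})
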