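# Discordant-pair selection, repetitiveness, anchor classification and
# predicted insertion intervals.

STATS <- library_stats(450, 40, 100, 0)

test_that("valid discordant pairs follow the distance and flag rules", {
  ## proper-pair flag wins
  p <- aln_tab(aln_row("q", start = 1000, proper = TRUE),
               aln_row("q", start = 3000, strand = "-", proper = TRUE))
  expect_false(is_valid_discordant(p, STATS))
  ## distance 2000 > 2 x 450
  p <- aln_tab(aln_row("q", start = 1000),
               aln_row("q", start = 3000, strand = "-"))
  expect_true(is_valid_discordant(p, STATS))
  ## different chromosomes
  p <- aln_tab(aln_row("q", chrom = "chr1", start = 1000),
               aln_row("q", chrom = "chr2", start = 1000))
  expect_true(is_valid_discordant(p, STATS))
  ## distance 500 <= 900
  p <- aln_tab(aln_row("q", start = 1000),
               aln_row("q", start = 1500, strand = "-"))
  expect_false(is_valid_discordant(p, STATS))
})

test_that("repetitive reads are mapq 0 or alt-hit carriers", {
  expect_true(is_repetitive(aln_row(mapq = 0L)))
  expect_true(is_repetitive(aln_row(mapq = 37L,
                                    xa = "chr2,+5001,100M,1;")))
  expect_false(is_repetitive(aln_row(mapq = 37L)))
})

test_that("predicted intervals follow the fragment-length geometry", {
  fwd <- aln_row(start = 1000, width = 100, strand = "+")
  iv <- predicted_interval(fwd, STATS, s_factor = 2)
  expect_equal(iv$lo, 1100)          # anchor end
  expect_equal(iv$hi, 1530)          # 1000 + 450 + 2 * 40

  rev <- aln_row(start = 2000, width = 100, strand = "-")
  iv <- predicted_interval(rev, STATS, s_factor = 2)
  expect_equal(iv$lo, 1570)          # 2100 - (450 + 80)
  expect_equal(iv$hi, 2000)          # anchor start

  iv <- predicted_interval(aln_row(start = 0, width = 100), STATS,
                           s_factor = 0)
  expect_equal(c(iv$lo, iv$hi), c(100, 450))

  ## anchor wider than the whole predicted reach: empty interval
  wide <- aln_row(start = 0, width = 600, strand = "+")
  expect_warning(iv <- predicted_interval(wide, STATS), "discarded")
  expect_null(iv)
})

test_that("anchor classification requires a unique non-TE anchor and a
           TE-hitting mate", {
  te <- small_te()
  params <- tei_params()
  ## mate primary placement inside ATCOPIA_1 (chr1:10000-12000)
  pair <- aln_tab(aln_row("q", start = 1000, mapq = 40L),
                  aln_row("q", start = 10500, strand = "-"))
  res <- classify_pair(pair, te, STATS, params)
  expect_equal(res$te_hits, "ATCOPIA_1")
  expect_equal(res$anchor$start, 1000)

  ## anchor mapq below threshold
  pair$mapq[1] <- 10L
  expect_null(classify_pair(pair, te, STATS, params))

  ## repetitive mate with alt hits in two TEs; anchor clean
  pair <- aln_tab(
    aln_row("q", start = 1000, mapq = 40L),
    aln_row("q", start = 200000, strand = "-", mapq = 0L,
            xa = "chr1,+50001,100M,2;chr2,+5001,100M,3;"))
  res <- classify_pair(pair, te, STATS, params)
  expect_equal(res$te_hits, c("ATLINE_2", "ATLINE_7"))

  ## anchor itself overlaps an annotated TE
  pair <- aln_tab(aln_row("q", start = 10100, mapq = 40L),
                  aln_row("q", start = 50500, strand = "-"))
  expect_null(classify_pair(pair, te, STATS, params))
})

test_that("the vectorised anchor extraction agrees with classify_pair", {
  te <- small_te()
  params <- tei_params()
  aln <- aln_tab(
    aln_row("q1", start = 1000, mapq = 40L, mchrom = "chr1",
            mstart = 10500),
    aln_row("q1", start = 10500, strand = "-", mchrom = "chr1",
            mstart = 1000),
    aln_row("q2", start = 2000, mapq = 10L, mchrom = "chr1",
            mstart = 10500),
    aln_row("q2", start = 10500, strand = "-", mchrom = "chr1",
            mstart = 2000),
    aln_row("q3", start = 3000, proper = TRUE, mchrom = "chr1",
            mstart = 3350),
    aln_row("q3", start = 3350, strand = "-", proper = TRUE,
            mchrom = "chr1", mstart = 3000))
  anc <- teiscan:::find_anchor_reads(aln, te, STATS, params)
  expect_equal(nrow(anc), 1L)
  expect_equal(anc$qname, "q1")
  expect_equal(anc$te_hits[[1]], "ATCOPIA_1")
  expect_equal(anc$ilo, 1100)
  expect_equal(anc$ihi, 1530)
  ## every emitted anchor is clean: non-repetitive, high mapq, TE-disjoint
  expect_true(all(anc$mapq >= params$mapq_min))
})
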