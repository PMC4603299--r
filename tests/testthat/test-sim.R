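# Synthetic genome, insertion planting, and the aligner-emulating read
# simulator.

test_that("the synthetic genome honours its construction contract", {
  sim <- make_sim_genome(c(chr1 = 1e6), n_families = 3,
                         copies_per_family = 10,
                         te_len_range = c(500, 3000), divergence = 0.02,
                         seed = 7)
  te <- sim$te_annotation
  expect_equal(nrow(te), 30L)
  expect_true(all(te$end - te$start >= 500))
  expect_equal(length(unique(te$family)), 3L)
  expect_equal(sum(nchar(sim$sequences)), 1e6)
  ## features inside the sequence, names unique
  expect_true(all(te$end <= nchar(sim$sequences[te$chrom])))
  expect_equal(anyDuplicated(te$name), 0L)

  ## determinism
  sim2 <- make_sim_genome(c(chr1 = 1e6), n_families = 3,
                          copies_per_family = 10,
                          te_len_range = c(500, 3000), divergence = 0.02,
                          seed = 7)
  expect_identical(sim$sequences, sim2$sequences)
  expect_identical(sim$te_annotation, sim2$te_annotation)

  ## divergence 0: all copies identical to the consensus
  sim0 <- make_sim_genome(c(chr1 = 5e5), n_families = 1,
                          copies_per_family = 3,
                          te_len_range = c(300, 300), divergence = 0,
                          seed = 3)
  te0 <- sim0$te_annotation
  copies <- substring(sim0$sequences[te0$chrom], te0$start + 1, te0$end)
  expect_equal(unique(copies), unname(sim0$te_library))
})

test_that("infeasible packing is an error", {
  expect_error(make_sim_genome(c(chr1 = 5e4), n_families = 3,
                               copies_per_family = 10,
                               te_len_range = c(2000, 3000), seed = 1),
               "infeasible")
})

test_that("planted insertions carry the designed allele fractions and
           respect exclusion zones", {
  sim <- make_sim_genome(c(chr1 = 1e6), seed = 21, n_families = 2,
                         copies_per_family = 5,
                         te_len_range = c(400, 1500))
  pl <- plant_insertions(sim, n_hom = 1, n_het = 1, seed = 22)
  expect_setequal(pl$truth$true_af, c(1.0, 0.5))
  expect_equal(pl$mode, "normal")
  expect_equal(unname(pl$weights), c(1, 1))

  td <- plant_insertions(sim, n_hom = 3, n_het = 3, n_lcf = 5, seed = 23)
  expect_equal(sum(td$truth$true_af == 0.25), 5L)
  expect_equal(td$mode, "tumor")
  expect_equal(unname(td$weights), c(2, 1, 1))

  ## every truth position is >= 100 bp from any annotated TE
  te <- sim$te_annotation
  for (i in seq_len(nrow(td$truth))) {
    d <- pmax(te$start - td$truth$position[i],
              td$truth$position[i] - te$end)
    expect_true(all(d[te$chrom == td$truth$chrom[i]] >= 100))
  }
  ## and insertions are mutually spaced
  pos <- sort(td$truth$position[td$truth$chrom == "chr1"])
  if (length(pos) > 1) expect_true(all(diff(pos) >= 2500))
})

test_that("zero fragment-length dispersion makes proper-pair TLEN exact", {
  sim <- make_sim_genome(c(chr1 = 2e5), n_families = 1,
                         copies_per_family = 3,
                         te_len_range = c(300, 600), seed = 31)
  pl <- plant_insertions(sim, n_hom = 1, n_het = 0, seed = 32,
                         min_spacing = 1000)
  res <- simulate_aligned_reads(
    pl, sim, sim_read_config(coverage = 10, fragment_sd = 0),
    seed = 33, keep_alignments = TRUE)
  aln <- res$alignments
  expect_true(all(abs(aln$tlen[aln$proper]) == 450))
})

test_that("homozygous insertions leave clipped reads but no spanning core
           reads; heterozygous leave both", {
  fx <- small_sim()
  aln <- fx$res$alignments
  tr <- fx$res$truth
  hom <- tr[tr$class == "hom", ][1, ]
  het <- tr[tr$class == "het", ][1, ]
  bp_hom <- find_breakpoint(aln, hom$chrom, hom$position - 50,
                            hom$position + 50)
  expect_equal(bp_hom$breakpoint, hom$position)
  expect_gt(bp_hom$support, 0)
  expect_equal(count_core_reads(aln, hom$chrom, hom$position), 0L)

  bp_het <- find_breakpoint(aln, het$chrom, het$position - 50,
                            het$position + 50)
  expect_equal(bp_het$breakpoint, het$position)
  expect_gt(count_core_reads(aln, het$chrom, het$position), 0L)
})

test_that("simulation output is deterministic and byte-identical for a
           fixed seed", {
  sim <- make_sim_genome(c(chr1 = 2e5), n_families = 1,
                         copies_per_family = 3,
                         te_len_range = c(300, 600), seed = 41)
  pl <- plant_insertions(sim, 2, 2, seed = 42, min_spacing = 1000)
  p1 <- tempfile("det1"); p2 <- tempfile("det2")
  r1 <- simulate_aligned_reads(pl, sim, sim_read_config(coverage = 8),
                               prefix = p1, seed = 43)
  r2 <- simulate_aligned_reads(pl, sim, sim_read_config(coverage = 8),
                               prefix = p2, seed = 43)
  expect_identical(unname(tools::md5sum(r1$bam)),
                   unname(tools::md5sum(r2$bam)))
})

test_that("BAM output round-trips through the reader", {
  sim <- make_sim_genome(c(chr1 = 2e5), n_families = 1,
                         copies_per_family = 3,
                         te_len_range = c(300, 600), seed = 51)
  pl <- plant_insertions(sim, 2, 1, seed = 52, min_spacing = 1000)
  res <- simulate_aligned_reads(pl, sim, sim_read_config(coverage = 6),
                                seed = 53, keep_alignments = TRUE)
  back <- read_bam_alignments(res$bam)
  orig <- res$alignments
  o1 <- orig[order(orig$chrom, orig$start, orig$qname, orig$first), ]
  o2 <- back[order(back$chrom, back$start, back$qname, back$first), ]
  for (col in c("chrom", "start", "end", "strand", "cigar", "proper",
                "lclip", "rclip", "tlen", "mstart")) {
    expect_equal(o2[[col]], o1[[col]], info = col)
  }
  ## alt-hit tags survive
  expect_equal(sort(o2$xa[!is.na(o2$xa)]), sort(o1$xa[!is.na(o1$xa)]))
})

test_that("recovered library statistics match the configured
           distribution", {
  fx <- small_sim()
  st <- estimate_library_stats(fx$res$alignments)
  n <- st$n_pairs_sampled
  expect_lt(abs(st$fragment_mean - 450), 3 * 40 / sqrt(n) + 1)
  expect_lt(abs(st$fragment_sd - 40), 5)
})
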