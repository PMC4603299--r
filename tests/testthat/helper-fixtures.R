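# Shared fixtures: alignment-row builders, a small TE index, and a
# memoised small end-to-end simulation (computed once per session).

aln_row <- function(qname = "r1", chrom = "chr1", start = 0, width = 100,
                    strand = "+", mapq = 37L, proper = FALSE, lclip = 0L,
                    rclip = 0L, mchrom = chrom, mstart = NA, tlen = 0L,
                    xa = NA_character_, first = TRUE) {
  cigar <- paste0(if (lclip > 0) paste0(lclip, "S"), width, "M",
                  if (rclip > 0) paste0(rclip, "S"))
  data.frame(qname = qname, flag = 0L, chrom = chrom, start = start,
             end = start + width, strand = strand, mapq = mapq,
             cigar = cigar, qwidth = width + lclip + rclip,
             lclip = as.integer(lclip), rclip = as.integer(rclip),
             proper = proper, first = first, mchrom = mchrom,
             mstart = mstart, tlen = as.integer(tlen), xa = xa,
             stringsAsFactors = FALSE)
}

aln_tab <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

## two annotated TEs on chr1, one on chr2
small_te <- function() {
  te_index(data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 50000, 5000),
    end = c(12000, 51500, 7000),
    strand = "+",
    name = c("ATCOPIA_1", "ATLINE_2", "ATLINE_7"),
    stringsAsFactors = FALSE))
}

## anchor table from raw predicted intervals (for clustering tests)
anchor_df <- function(ilo, ihi, start = ilo, end = start + 100,
                      strand = "+", te_hits = "TE_1") {
  n <- length(ilo)
  df <- data.frame(qname = paste0("a", seq_len(n)), chrom = "chr1",
                   start = start, end = end, strand = strand, mapq = 37L,
                   ilo = ilo, ihi = ihi, stringsAsFactors = FALSE)
  df$te_hits <- rep(list(te_hits), n)
  df
}

## hand-built cluster-pair object (insertion_interval / metrics tests)
mk_pair <- function(fwd_starts, rev_ends, fwd_te = "A_1", rev_te = "A_1",
                    chrom = "chr1") {
  mk <- function(starts, ends, te) {
    list(chrom = chrom, idx = seq_along(starts), lo = min(starts),
         hi = max(ends), size = length(starts),
         span = max(starts) - min(starts), starts = starts, ends = ends,
         qnames = paste0("r", seq_along(starts)), te_names = te)
  }
  list(fwd = mk(fwd_starts, fwd_starts + 100, fwd_te),
       rev = mk(rev_ends - 100, rev_ends, rev_te),
       chrom = chrom)
}

## brute-force clustering oracle: maximal cliques of the closed-interval
## overlap graph via igraph, then the same isolation rule (shared member
## or overlapping intersection intervals)
oracle_clusters <- function(lo, hi) {
  n <- length(lo)
  cliques <- if (n == 1L) list(1L) else {
    adj <- outer(lo, hi, `<=`) & outer(hi, lo, `>=`)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    lapply(igraph::max_cliques(g), function(v) sort(as.integer(v)))
  }
  m <- length(cliques)
  clo <- vapply(cliques, function(v) max(lo[v]), 0)
  chi <- vapply(cliques, function(v) min(hi[v]), 0)
  bad <- logical(m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        shared <- length(intersect(cliques[[i]], cliques[[j]])) > 0L
        ovl <- clo[i] <= chi[j] && clo[j] <= chi[i]
        if (shared || ovl) bad[c(i, j)] <- TRUE
      }
    }
  }
  cliques[!bad]
}

## canonical representation of a cluster list for set comparison
cluster_sets <- function(clusters) {
  sets <- lapply(clusters, function(cl) sort(cl$idx))
  sets[order(vapply(sets, paste, "", collapse = ","))]
}

## memoised small simulation shared across test files
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    sim <- make_sim_genome(c(chr1 = 4e5), n_families = 2,
                           copies_per_family = 4,
                           te_len_range = c(400, 1200), seed = 101)
    pl <- plant_insertions(sim, n_hom = 6, n_het = 6, seed = 102)
    res <- simulate_aligned_reads(pl, sim, sim_read_config(coverage = 20),
                                  prefix = tempfile("smallsim"),
                                  seed = 103, keep_alignments = TRUE)
    .fixture_env$small <- list(sim = sim, pl = pl, res = res)
  }
  .fixture_env$small
}

## reverse-complement an alignment table and TE index on a single
## chromosome of length L (strand-mirror symmetry checks)
mirror_cigar <- function(cig) {
  vapply(cig, function(x) {
    toks <- regmatches(x, gregexpr("\\d+[A-Z=]", x))[[1]]
    paste(rev(toks), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

mirror_xa <- function(xa, L) {
  vapply(xa, function(x) {
    if (is.na(x)) return(NA_character_)
    entries <- strsplit(x, ";", fixed = TRUE)[[1]]
    out <- vapply(entries, function(e) {
      f <- strsplit(e, ",", fixed = TRUE)[[1]]
      w <- teiscan:::parse_cigar(f[3])$ref_width
      pos0 <- as.integer(substring(f[2], 2)) - 1L
      ns <- if (substr(f[2], 1, 1) == "+") "-" else "+"
      paste0(f[1], ",", ns, L - (pos0 + w) + 1L, ",", mirror_cigar(f[3]),
             ",", f[4])
    }, character(1))
    paste0(out, ";", collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

mirror_aln <- function(aln, L) {
  m <- aln
  m$start <- L - aln$end
  m$end <- L - aln$start
  m$strand <- ifelse(aln$strand == "+", "-", "+")
  m$lclip <- aln$rclip
  m$rclip <- aln$lclip
  m$cigar <- mirror_cigar(aln$cigar)
  mate <- match(paste(aln$qname, !aln$first), paste(aln$qname, aln$first))
  m$mstart <- L - aln$end[mate]
  m$tlen <- -aln$tlen
  m$xa <- mirror_xa(aln$xa, L)
  m
}

mirror_te <- function(te, L) {
  out <- data.frame(chrom = te$chrom, start = L - te$end,
                    end = L - te$start,
                    strand = ifelse(te$strand == "+", "-", "+"),
                    name = te$name, family = te$family,
                    stringsAsFactors = FALSE)
  te_index(out[order(out$start), ])
}

## memoised desk-scale benchmark shared by the acceptance tests: the
## two-allele (normal) and four-allele (tumor) designs on one 3 Mb genome
acceptance_fixture <- function(seed = 314L) {
  key <- paste0("acc", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- make_sim_genome(seed = seed)
    td_pl <- plant_insertions(sim, n_hom = 75, n_het = 75, n_lcf = 73,
                              seed = seed + 1L)
    nd_pl <- as_normal_planting(td_pl)
    nd <- lapply(c(`10` = 10, `20` = 20, `40` = 40), function(cv) {
      sim_call_benchmark(sim, nd_pl, cv, seed = seed + 10L + cv)
    })
    td20 <- sim_call_benchmark(sim, td_pl, 20, seed = seed + 100L)
    td40 <- sim_call_benchmark(sim, td_pl, 40, seed = seed + 101L)
    som <- benchmark_somatic_pair(sim, td_pl, coverage = 40,
                                  seed = seed + 200L)
    .fixture_env[[key]] <- list(sim = sim, td_pl = td_pl, nd_pl = nd_pl,
                                nd = nd, td20 = td20, td40 = td40,
                                som = som)
  }
  .fixture_env[[key]]
}
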