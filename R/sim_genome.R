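# Synthetic genome generator: random background with planted multi-copy TE
# families, and construction of insertion alleles with exact liftover maps.

.FAMILY_POOL <- c("COPIA", "GYPSY", "LINE", "HAT", "MUTATOR", "MARINER",
                  "HARBINGER", "CACTA")

#' Generate a synthetic genome with multi-copy TE families
#'
#' Builds a random background sequence with planted TE copies. Each family
#' has one random consensus; copies are the consensus with substitutions at
#' the given per-base divergence, so a newly inserted copy is similar to the
#' other annotated copies of its family -- the premise that lets discordant
#' TE-mate reads find an annotated homolog. Deterministic for a fixed seed.
#'
#' @param genome_len Named numeric vector of chromosome lengths in bp
#'   (default `c(chr1 = 3e6)`).
#' @param n_families Number of TE families (default 3).
#' @param copies_per_family Annotated copies per family (default 10).
#' @param te_len_range Family consensus length range in bp; minimum must be
#'   >= 200 (default `c(500, 3000)`).
#' @param divergence Per-base substitution divergence of copies from their
#'   consensus (default 0.02).
#' @param min_te_gap Minimum background gap between planted copies in bp
#'   (default 2000).
#' @param seed Optional integer seed.
#' @return An object of class `sim_genome`: list with `sequences` (named
#'   character vector), `te_annotation` (a `te_index`), `te_library`
#'   (named consensus vector) and the generator parameters.
#' @export
make_sim_genome <- function(genome_len = c(chr1 = 3e6), n_families = 3,
                            copies_per_family = 10,
                            te_len_range = c(500, 3000), divergence = 0.02,
                            min_te_gap = 2000, seed = NULL) {
  stopifnot(length(genome_len) >= 1, !is.null(names(genome_len)),
            te_len_range[1] >= 200, te_len_range[2] >= te_len_range[1],
            divergence >= 0, divergence <= 1)
  if (!is.null(seed)) set.seed(seed)

  fam_names <- if (n_families <= length(.FAMILY_POOL)) {
    .FAMILY_POOL[seq_len(n_families)]
  } else {
    c(.FAMILY_POOL, paste0("FAM", seq_len(n_families - length(.FAMILY_POOL))))
  }
  fam_len <- round(runif(n_families, te_len_range[1], te_len_range[2]))
  te_library <- stats::setNames(
    vapply(fam_len, random_dna, character(1)), fam_names)

  ## copies assigned to chromosomes proportionally to length
  n_copies <- n_families * copies_per_family
  fam_of_copy <- sample(rep(seq_len(n_families), copies_per_family))
  chrom_of_copy <- sample(names(genome_len), n_copies, replace = TRUE,
                          prob = genome_len / sum(genome_len))

  ann <- list(); seqs <- character(0)
  copy_counter <- stats::setNames(integer(n_families), fam_names)
  for (chrom in names(genome_len)) {
    L <- genome_len[[chrom]]
    idx <- which(chrom_of_copy == chrom)
    fams <- fam_of_copy[idx]
    te_len <- fam_len[fams]
    k <- length(idx)
    bg <- L - sum(te_len)
    if (bg < (k + 1) * min_te_gap) {
      stop("infeasible packing: chromosome ", chrom,
           " too short for ", k, " TE copies with min gap ", min_te_gap,
           call. = FALSE)
    }
    extra <- as.vector(stats::rmultinom(1, bg - (k + 1) * min_te_gap,
                                        rep(1, k + 1)))
    gaps <- min_te_gap + extra
    pieces <- character(2 * k + 1)
    pieces[seq(1, 2 * k + 1, by = 2)] <- vapply(gaps, random_dna,
                                                character(1))
    te_seq <- mutate_dna(te_library[fams], divergence)
    if (k > 0) pieces[seq(2, 2 * k, by = 2)] <- te_seq
    seqs[chrom] <- paste(pieces, collapse = "")
    if (k > 0) {
      cum <- cumsum(nchar(pieces))
      te_piece_idx <- seq(2, 2 * k, by = 2)
      starts <- cum[te_piece_idx - 1L]
      ends <- cum[te_piece_idx]
      nums <- integer(k)
      for (j in seq_len(k)) {
        copy_counter[fams[j]] <- copy_counter[fams[j]] + 1L
        nums[j] <- copy_counter[fams[j]]
      }
      ann[[chrom]] <- data.frame(
        chrom = chrom, start = starts, end = ends, strand = "+",
        name = paste0(fam_names[fams], "_", nums),
        family = fam_names[fams], stringsAsFactors = FALSE)
    }
  }
  te_annotation <- te_index(do.call(rbind, ann))
  rownames(te_annotation) <- NULL
  structure(list(sequences = seqs, te_annotation = te_annotation,
                 te_library = te_library,
                 params = list(genome_len = genome_len,
                               n_families = n_families,
                               copies_per_family = copies_per_family,
                               te_len_range = te_len_range,
                               divergence = divergence,
                               min_te_gap = min_te_gap, seed = seed)),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d sequence(s), %s bp total; %d TE copies in %d families\n",
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ","),
              nrow(x$te_annotation), length(x$te_library)))
  invisible(x)
}

# insertion planting ----------------------------------------------------

## allele = segment table with exact liftover between allele and reference
## coordinates. Columns: chrom, type ("ref"|"te"), ref_start, ref_end,
## donor_start, donor_end, ins_point, te_name, alo, ahi (allele coords,
## per chromosome).
build_allele <- function(sim, events) {
  segs <- list()
  for (chrom in names(sim$sequences)) {
    L <- nchar(sim$sequences[[chrom]])
    ev <- events[events$chrom == chrom, , drop = FALSE]
    ev <- ev[order(ev$position), , drop = FALSE]
    bnd <- c(0, rep(ev$position, each = 1), L)
    rows <- list()
    prev <- 0
    for (j in seq_len(nrow(ev))) {
      p <- ev$position[j]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, type = "ref", ref_start = prev, ref_end = p,
        donor_start = NA_real_, donor_end = NA_real_,
        donor_chrom = NA_character_, ins_point = NA_real_,
        te_name = NA_character_)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, type = "te", ref_start = NA_real_,
        ref_end = NA_real_, donor_start = ev$donor_start[j],
        donor_end = ev$donor_end[j], donor_chrom = ev$donor_chrom[j],
        ins_point = p, te_name = ev$te_name[j])
      prev <- p
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, type = "ref", ref_start = prev, ref_end = L,
      donor_start = NA_real_, donor_end = NA_real_,
      donor_chrom = NA_character_, ins_point = NA_real_,
      te_name = NA_character_)
    df <- do.call(rbind, rows)
    len <- ifelse(df$type == "ref", df$ref_end - df$ref_start,
                  df$donor_end - df$donor_start)
    df$ahi <- cumsum(len)
    df$alo <- df$ahi - len
    segs[[chrom]] <- df
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Plant TE insertions and build the sample alleles
#'
#' Chooses donor TEs (uniformly among annotated copies >= 200 bp, with
#' replacement) and insertion loci (excluding regions within `min_dist_te`
#' bp of annotated TEs or N runs, and at least `min_spacing` bp apart), and
#' assembles the sample's allele sequences as copy-paste insertions of the
#' donor sequence with exact liftover maps.
#'
#' Normal design (`n_lcf = 0`): two alleles -- homozygous insertions in
#' both, heterozygous in one, so true allele fractions are 1.0 and 0.5.
#' Tumor design (`n_lcf > 0`): four allele copies (2x allele1, allele2,
#' allele3) so that low-cell-fraction insertions, carried only by allele3,
#' have true allele fraction 0.25.
#'
#' @param sim A [make_sim_genome()] object.
#' @param n_hom,n_het,n_lcf Numbers of homozygous, heterozygous and
#'   low-cell-fraction insertions.
#' @param min_dist_te Exclusion distance around annotated TEs and N runs in
#'   bp (default 100).
#' @param min_spacing Minimum distance between planted insertion points in
#'   bp (default 2500), so that each event is independently resolvable at
#'   desk scale.
#' @param edge_margin Minimum distance from chromosome ends (default 2000).
#' @param seed Optional integer seed.
#' @return An object of class `tei_planting`: list with `alleles` (list of
#'   segment tables), `weights` (allele copy numbers), `truth` (data.frame
#'   with `chrom`, `position`, `te_name`, `family`, `true_af`, `class`)
#'   and `mode` (`"normal"` or `"tumor"`).
#' @export
plant_insertions <- function(sim, n_hom, n_het, n_lcf = 0,
                             min_dist_te = 100, min_spacing = 2500,
                             edge_margin = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_total <- n_hom + n_het + n_lcf
  stopifnot(n_total >= 1)
  te <- sim$te_annotation
  donors_ok <- which(te$end - te$start >= 200)
  if (length(donors_ok) == 0L) stop("no donor TE >= 200 bp", call. = FALSE)

  ## exclusion zones: annotated TEs and N runs, padded
  excl <- data.frame(chrom = te$chrom,
                     lo = te$start - min_dist_te,
                     hi = te$end + min_dist_te)
  for (chrom in names(sim$sequences)) {
    m <- gregexpr("N+", sim$sequences[[chrom]])[[1]]
    if (m[1] != -1L) {
      excl <- rbind(excl, data.frame(
        chrom = chrom, lo = as.integer(m) - 1L - min_dist_te,
        hi = as.integer(m) - 1L + attr(m, "match.length") + min_dist_te))
    }
  }

  lens <- vapply(sim$sequences, nchar, 0L)
  positions <- data.frame(chrom = character(0), position = numeric(0))
  attempts <- 0L
  while (nrow(positions) < n_total) {
    attempts <- attempts + 1L
    if (attempts > 200L) {
      stop("exhausted placement attempts: genome too crowded for ",
           n_total, " insertions with spacing ", min_spacing,
           call. = FALSE)
    }
    need <- n_total - nrow(positions)
    chrom <- sample(names(lens), need, replace = TRUE,
                    prob = lens / sum(lens))
    pos <- floor(runif(need, edge_margin, lens[chrom] - edge_margin))
    cand <- data.frame(chrom = chrom, position = pos)
    for (i in seq_len(nrow(cand))) {
      e <- excl[excl$chrom == cand$chrom[i], , drop = FALSE]
      if (any(cand$position[i] >= e$lo & cand$position[i] < e$hi)) next
      near <- positions$chrom == cand$chrom[i] &
        abs(positions$position - cand$position[i]) < min_spacing
      if (any(near)) next
      positions <- rbind(positions, cand[i, ])
    }
  }
  positions <- positions[sample.int(n_total), , drop = FALSE]

  donor <- sample(donors_ok, n_total, replace = TRUE)
  events <- data.frame(chrom = positions$chrom,
                       position = positions$position,
                       te_name = te$name[donor],
                       family = te$family[donor],
                       donor_start = te$start[donor],
                       donor_end = te$end[donor],
                       donor_chrom = te$chrom[donor],
                       class = rep(c("hom", "het", "lcf"),
                                   c(n_hom, n_het, n_lcf)),
                       stringsAsFactors = FALSE)

  mode <- if (n_lcf > 0) "tumor" else "normal"
  hom_ev <- events[events$class == "hom", , drop = FALSE]
  het_ev <- events[events$class %in% c("hom", "het"), , drop = FALSE]
  if (mode == "normal") {
    alleles <- list(a1 = build_allele(sim, hom_ev),
                    a2 = build_allele(sim, het_ev))
    weights <- c(a1 = 1, a2 = 1)
  } else {
    alleles <- list(a1 = build_allele(sim, hom_ev),
                    a2 = build_allele(sim, het_ev),
                    a3 = build_allele(sim, events))
    weights <- c(a1 = 2, a2 = 1, a3 = 1)
  }
  af <- c(hom = 1.0, het = 0.5, lcf = 0.25)
  truth <- data.frame(chrom = events$chrom, position = events$position,
                      te_name = events$te_name, family = events$family,
                      true_af = unname(af[events$class]),
                      class = events$class, stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$position), ]
  rownames(truth) <- NULL
  structure(list(alleles = alleles, weights = weights, truth = truth,
                 mode = mode),
            class = "tei_planting")
}

#' Matched-normal planting from a tumor planting
#'
#' Derives the normal-sample (ND) design from a tumor (TD) planting: the
#' same homozygous and heterozygous germline insertions on two allele
#' copies, without the tumor-only low-cell-fraction allele. Simulating
#' reads from both objects yields a matched TD/ND pair sharing germline
#' events.
#'
#' @param planting A tumor-mode [plant_insertions()] object.
#' @return A `tei_planting` in normal mode.
#' @export
as_normal_planting <- function(planting) {
  stopifnot(inherits(planting, "tei_planting"))
  if (planting$mode != "tumor") return(planting)
  structure(list(alleles = planting$alleles[c("a1", "a2")],
                 weights = c(a1 = 1, a2 = 1),
                 truth = planting$truth[planting$truth$class != "lcf", ,
                                        drop = FALSE],
                 mode = "normal"),
            class = "tei_planting")
}

## Assemble the nucleotide sequence of one allele chromosome from its
## segment table (used for FASTQ export and sequence-emitting simulation).
allele_sequence <- function(sim, allele, chrom) {
  segs <- allele[allele$chrom == chrom, , drop = FALSE]
  ref <- sim$sequences[[chrom]]
  pieces <- character(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    pieces[i] <- if (segs$type[i] == "ref") {
      substr(ref, segs$ref_start[i] + 1L, segs$ref_end[i])
    } else {
      substr(sim$sequences[[segs$donor_chrom[i]]],
             segs$donor_start[i] + 1L, segs$donor_end[i])
    }
  }
  paste(pieces, collapse = "")
}

#' Write the reference and annotations of a simulated genome
#'
#' Writes `<prefix>.fa` (reference FASTA), `<prefix>.te.gff3` (TE
#' annotation) and, when a planting is supplied, `<prefix>.truth.gff3`
#' (one feature per planted insertion with a `true_af` attribute).
#'
#' @param sim A `sim_genome`.
#' @param prefix Output path prefix.
#' @param planting Optional `tei_planting` with the truth records.
#' @return Invisibly, the vector of written paths.
#' @export
export_reference <- function(sim, prefix, planting = NULL) {
  fa <- paste0(prefix, ".fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$sequences), fa)
  gff <- paste0(prefix, ".te.gff3")
  write_te_annotation(sim$te_annotation, gff)
  paths <- c(fa, gff)
  if (!is.null(planting)) {
    tr <- planting$truth
    gr <- GenomicRanges::GRanges(tr$chrom,
                                 IRanges::IRanges(tr$position + 1L,
                                                  tr$position + 1L))
    S4Vectors::mcols(gr)$source <- "teiscan"
    S4Vectors::mcols(gr)$type <- "TE_insertion"
    S4Vectors::mcols(gr)$Name <- tr$te_name
    S4Vectors::mcols(gr)$true_af <- tr$true_af
    tp <- paste0(prefix, ".truth.gff3")
    rtracklayer::export(gr, tp, format = "gff3")
    paths <- c(paths, tp)
  }
  invisible(paths)
}
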