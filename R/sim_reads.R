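# Aligner-emulating paired-end read simulation from planted-insertion
# alleles. Fragments are drawn per allele in proportion to allele copy
# number; each read is rendered as an alignment against the REFERENCE via
# the exact liftover, reproducing the mapping signatures a short-read
# aligner produces at an insertion:
#   * reads fully in non-inserted sequence -> proper pairs at true positions
#   * reads fully inside an inserted TE    -> placed at the donor copy,
#     with alternative-hit entries at the other family copies and mapq 0
#     when the placement is ambiguous
#   * reads crossing an insertion junction -> soft-clipped at the insertion
#     point, the longer segment mapped (to the flank, or into the donor)

#' Read-simulation configuration
#'
#' @param coverage Total fold-coverage across all allele copies.
#' @param fragment_mean,fragment_sd Fragment length distribution in bp
#'   (default 450 +/- 40).
#' @param read_len Read length in bp (default 100).
#' @param substitution_rate Per-base substitution error rate applied when
#'   sequences are emitted; must be in `[0, 0.1]`. Errors do not alter the
#'   emulated placements (default 0.005).
#' @param proper_tlen_mult Template lengths within this many fragment sds
#'   of the mean are flagged proper (default 4).
#' @return A list of class `sim_read_config`.
#' @export
sim_read_config <- function(coverage = 20, fragment_mean = 450,
                            fragment_sd = 40, read_len = 100,
                            substitution_rate = 0.005,
                            proper_tlen_mult = 4) {
  stopifnot(coverage > 0, fragment_mean > 0, fragment_sd >= 0,
            read_len > 0, substitution_rate >= 0, substitution_rate <= 0.1)
  structure(list(coverage = coverage, fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd, read_len = read_len,
                 substitution_rate = substitution_rate,
                 proper_tlen_mult = proper_tlen_mult),
            class = "sim_read_config")
}

## Map read intervals [s, e) in allele coordinates of one chromosome onto
## the reference. Returns a data.frame: chrom, start (0-based), mlen,
## lclip, rclip, in_te, te_name, te_off (offset of the mapped segment
## within the donor TE). Vectorised; a read never spans more than two
## liftover segments because TE copies are longer than a read and planted
## insertions are widely spaced.
.map_reads <- function(segs, read_chrom, s, e) {
  n <- length(s)
  si <- findInterval(s, segs$alo)
  sj <- findInterval(e - 1, segs$alo)
  if (any(sj > si + 1L)) {
    stop("read spans more than two liftover segments; TE copies shorter ",
         "than a read are not supported", call. = FALSE)
  }
  chrom <- rep(read_chrom, n)
  start <- numeric(n); mlen <- integer(n)
  lclip <- integer(n); rclip <- integer(n)
  in_te <- logical(n); te_name <- rep(NA_character_, n)
  te_off <- rep(NA_real_, n)
  rl <- as.integer(e - s)

  same <- si == sj
  ref_seg <- segs$type[si] == "ref"
  ## fully inside a reference segment
  m <- same & ref_seg
  start[m] <- segs$ref_start[si[m]] + (s[m] - segs$alo[si[m]])
  mlen[m] <- rl[m]
  ## fully inside an inserted TE: placed at the donor copy
  m <- same & !ref_seg
  off <- s[m] - segs$alo[si[m]]
  start[m] <- segs$donor_start[si[m]] + off
  chrom[m] <- segs$donor_chrom[si[m]]
  mlen[m] <- rl[m]
  in_te[m] <- TRUE
  te_name[m] <- segs$te_name[si[m]]
  te_off[m] <- off

  cross <- which(si != sj)
  if (length(cross)) {
    b <- segs$alo[sj[cross]]          # boundary in allele coords
    A <- as.integer(b - s[cross])     # left-segment part
    B <- as.integer(e[cross] - b)     # right-segment part
    left_ref <- segs$type[si[cross]] == "ref"

    ## ref -> te: left junction at ins_point p
    idx <- cross[left_ref]
    if (length(idx)) {
      a <- A[left_ref]; bb <- B[left_ref]
      p <- segs$ins_point[sj[idx]]
      flank <- a >= bb                # longer (or tied) segment in flank
      i1 <- idx[flank]
      start[i1] <- p[flank] - a[flank]
      mlen[i1] <- a[flank]; rclip[i1] <- bb[flank]
      i2 <- idx[!flank]
      start[i2] <- segs$donor_start[sj[i2]]
      chrom[i2] <- segs$donor_chrom[sj[i2]]
      mlen[i2] <- bb[!flank]; lclip[i2] <- a[!flank]
      in_te[i2] <- TRUE
      te_name[i2] <- segs$te_name[sj[i2]]
      te_off[i2] <- 0
    }
    ## te -> ref: right junction at ins_point p of the left (te) segment
    idx <- cross[!left_ref]
    if (length(idx)) {
      a <- A[!left_ref]; bb <- B[!left_ref]
      p <- segs$ins_point[si[idx]]
      flank <- bb >= a
      i1 <- idx[flank]
      start[i1] <- p[flank]
      mlen[i1] <- bb[flank]; lclip[i1] <- a[flank]
      i2 <- idx[!flank]
      off2 <- segs$donor_end[si[i2]] - segs$donor_start[si[i2]] - a[!flank]
      start[i2] <- segs$donor_start[si[i2]] + off2
      chrom[i2] <- segs$donor_chrom[si[i2]]
      mlen[i2] <- a[!flank]; rclip[i2] <- bb[!flank]
      in_te[i2] <- TRUE
      te_name[i2] <- segs$te_name[si[i2]]
      te_off[i2] <- off2
    }
  }
  data.frame(chrom = chrom, start = start, mlen = mlen, lclip = lclip,
             rclip = rclip, in_te = in_te, te_name = te_name,
             te_off = te_off, stringsAsFactors = FALSE)
}

## alternative-hit strings for reads placed inside a TE: the equivalent
## offset in every other copy of the same family (vectorised).
.xa_strings <- function(te, te_name, te_off, mlen, lclip, rclip,
                        divergence) {
  out <- rep(NA_character_, length(te_name))
  placed <- which(!is.na(te_name))
  if (length(placed) == 0L) return(out)
  other_rows <- lapply(seq_len(nrow(te)), function(i) {
    setdiff(which(te$family == te$family[i]), i)
  })
  names(other_rows) <- te$name
  rows_list <- other_rows[te_name[placed]]
  reps <- lengths(rows_list)
  has <- reps > 0L
  pl <- placed[has]
  if (length(pl) == 0L) return(out)
  reps <- reps[has]
  trow <- unlist(rows_list[has], use.names = FALSE)
  ridx <- rep(seq_along(pl), reps)
  cig <- paste0(ifelse(lclip[pl] > 0, paste0(lclip[pl], "S"), ""),
                mlen[pl], "M",
                ifelse(rclip[pl] > 0, paste0(rclip[pl], "S"), ""))
  nm <- round(divergence * mlen[pl])
  entry <- paste0(te$chrom[trow], ",+",
                  te$start[trow] + te_off[pl][ridx] + 1, ",",
                  cig[ridx], ",", nm[ridx], ";")
  grp <- factor(ridx, levels = seq_along(pl))
  out[pl] <- vapply(split(entry, grp), paste0, character(1),
                    collapse = "")
  out
}

#' Simulate aligner-style paired-end alignments from planted alleles
#'
#' Draws fragments from each allele (in proportion to its copy number) with
#' normal fragment lengths, maps every read onto the reference through the
#' allele's liftover, and writes a coordinate-sorted, indexed BAM with
#' proper-pair flags, template lengths, soft-clip CIGARs, mapping qualities
#' and alternative-hit tags set consistently. Deterministic for a fixed
#' seed.
#'
#' @param planting A [plant_insertions()] object.
#' @param sim The [make_sim_genome()] genome it was planted in.
#' @param cfg A [sim_read_config()].
#' @param prefix Output path prefix for `<prefix>.bam`; a temporary path by
#'   default.
#' @param seed Optional integer seed.
#' @param emit_sequences When `TRUE`, read sequences (with substitution
#'   errors) and qualities are written; by default SEQ/QUAL are `*`, which
#'   the caller never consumes.
#' @param fastq When `TRUE` (implies `emit_sequences`), also writes
#'   `<prefix>_1.fq` / `<prefix>_2.fq` for end-to-end runs through a real
#'   aligner.
#' @param keep_alignments When `TRUE`, the in-memory alignment table is
#'   returned as `$alignments`.
#' @return List of class `tei_sim`: `bam` (path), `truth`, `stats` (the
#'   configured [library_stats()]), `targets`, `n_fragments`, and
#'   optionally `alignments`.
#' @export
simulate_aligned_reads <- function(planting, sim, cfg = sim_read_config(),
                                   prefix = tempfile("teisim"),
                                   seed = NULL, emit_sequences = FALSE,
                                   fastq = FALSE, keep_alignments = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (fastq) emit_sequences <- TRUE
  rl <- cfg$read_len
  wsum <- sum(planting$weights)
  te <- sim$te_annotation
  parts <- list()
  for (ai in seq_along(planting$alleles)) {
    allele <- planting$alleles[[ai]]
    cov_a <- cfg$coverage * planting$weights[ai] / wsum
    for (chrom in unique(allele$chrom)) {
      segs <- allele[allele$chrom == chrom, , drop = FALSE]
      La <- max(segs$ahi)
      nfrag <- round(cov_a * La / (2 * rl))
      if (nfrag == 0L) next
      flen <- pmax(rl + 10, round(rnorm(nfrag, cfg$fragment_mean,
                                        cfg$fragment_sd)))
      flen <- pmin(flen, La)
      fstart <- floor(runif(nfrag, 0, La - flen + 1))
      s1 <- fstart; e1 <- fstart + rl
      s2 <- fstart + flen - rl; e2 <- fstart + flen
      m1 <- .map_reads(segs, chrom, s1, e1)
      m2 <- .map_reads(segs, chrom, s2, e2)

      same_chrom <- m1$chrom == m2$chrom
      span_lo <- pmin(m1$start, m2$start)
      span_hi <- pmax(m1$start + m1$mlen, m2$start + m2$mlen)
      span <- span_hi - span_lo
      tol <- cfg$proper_tlen_mult * cfg$fragment_sd
      proper <- same_chrom & !m1$in_te & !m2$in_te &
        m1$start <= m2$start &
        abs(span - cfg$fragment_mean) <= tol
      ## TLEN: outer span, positive on the leftmost read; 0 across chroms
      tl1 <- ifelse(same_chrom,
                    ifelse(m1$start <= m2$start, span, -span), 0L)
      qname <- sprintf("a%d%s_%07d", ai, chrom, seq_len(nfrag))

      mk <- function(m, mo, strand, first, tlen, s_allele) {
        cig <- paste0(ifelse(m$lclip > 0, paste0(m$lclip, "S"), ""),
                      m$mlen, "M",
                      ifelse(m$rclip > 0, paste0(m$rclip, "S"), ""))
        df <- data.frame(
          qname = qname, chrom = m$chrom, start = m$start,
          end = m$start + m$mlen, strand = strand, mapq = 37L,
          cigar = cig, qwidth = rl, lclip = m$lclip, rclip = m$rclip,
          proper = proper, first = first, mchrom = mo$chrom,
          mstart = mo$start, tlen = as.integer(tlen),
          xa = .xa_strings(te, m$te_name, m$te_off, m$mlen, m$lclip,
                           m$rclip, sim$params$divergence),
          mstrand = if (strand == "+") "-" else "+",
          s_allele = s_allele,
          stringsAsFactors = FALSE)
        df$mapq[!is.na(df$xa)] <- 0L
        df
      }
      r1 <- mk(m1, m2, "+", TRUE, tl1, s1)
      r2 <- mk(m2, m1, "-", FALSE, -tl1, s2)
      if (emit_sequences) {
        aseq <- allele_sequence(sim, allele, chrom)
        r1$seq <- mutate_dna(substring(aseq, s1 + 1, e1),
                             cfg$substitution_rate)
        r2$seq <- mutate_dna(substring(aseq, s2 + 1, e2),
                             cfg$substitution_rate)
        r1$qual <- r2$qual <- strrep("I", rl)
      }
      parts[[length(parts) + 1L]] <- r1
      parts[[length(parts) + 1L]] <- r2
    }
  }
  aln <- do.call(rbind, parts)
  aln$s_allele <- NULL
  targets <- vapply(sim$sequences, nchar, 0L)
  if (fastq) .write_fastq(aln, prefix)
  bam <- write_bam_alignments(aln, targets, prefix)
  out <- list(bam = bam, truth = planting$truth,
              stats = library_stats(cfg$fragment_mean, cfg$fragment_sd,
                                    rl, 0, NA),
              targets = targets,
              n_fragments = nrow(aln) / 2L,
              mode = planting$mode)
  if (keep_alignments) out$alignments <- aln
  structure(out, class = "tei_sim")
}

.write_fastq <- function(aln, prefix) {
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  }
  for (mate in 1:2) {
    sel <- if (mate == 1) aln$first else !aln$first
    sub <- aln[sel, , drop = FALSE]
    seq <- ifelse(sub$strand == "-", revcomp(sub$seq), sub$seq)
    lines <- as.vector(rbind(paste0("@", sub$qname), seq, "+", sub$qual))
    writeLines(lines, sprintf("%s_%d.fq", prefix, mate))
  }
}
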