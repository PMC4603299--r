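# Discordant-pair selection, anchor classification and predicted insertion
# intervals.

#' Is a read pair a valid discordant pair?
#'
#' A pair is a valid discordant candidate when it is not flagged as a proper
#' pair and the two reads map either to different chromosomes or at a
#' mapping distance greater than twice the mean fragment length. Mapping
#' distance is the difference between the leftmost coordinates of the two
#' reads.
#'
#' @param pair Alignment table with exactly two rows (the two primary
#'   records of one read pair).
#' @param stats A [library_stats()] object.
#' @return Logical scalar.
#' @export
is_valid_discordant <- function(pair, stats) {
  stopifnot(nrow(pair) == 2L)
  if (any(pair$proper)) return(FALSE)
  if (pair$chrom[1] != pair$chrom[2]) return(TRUE)
  abs(pair$start[1] - pair$start[2]) > 2 * stats$fragment_mean
}

#' Is a read repetitively mapped?
#'
#' A read is considered repetitive when its mapping quality is 0 or when it
#' carries alternative-hit placements (XA-style tag). Aligners assign their
#' lowest score to reads with several equally good placements, and record
#' near-equivalent ones in the alternative-hit tag.
#'
#' @param read One-row alignment table (or list) with `mapq` and `xa`.
#' @return Logical scalar.
#' @export
is_repetitive <- function(read) {
  mapq <- read$mapq
  xa <- read$xa
  isTRUE(mapq == 0L) || (!is.na(xa) && nzchar(xa))
}

#' Predicted insertion interval of an anchor read
#'
#' A discordant anchor read predicts an insertion downstream of itself
#' (relative to its strand) within an interval whose far bound lies one
#' fragment length plus `s_factor` fragment-length standard deviations away
#' from the anchor start, and whose near bound is the anchor's inner edge.
#'
#' @param anchor One-row alignment table (or list) with `chrom`, `start`,
#'   `end`, `strand`.
#' @param stats A [library_stats()] object.
#' @param s_factor Multiplier of the fragment-length sd (default 2).
#' @return Named list `(chrom, lo, hi)` with `lo < hi`, or `NULL` (with a
#'   warning) if the library statistics make the interval empty.
#' @export
predicted_interval <- function(anchor, stats, s_factor = 2) {
  reach <- stats$fragment_mean + s_factor * stats$fragment_sd
  if (anchor$strand == "+") {
    lo <- anchor$end
    hi <- anchor$start + reach
  } else {
    lo <- anchor$end - reach
    hi <- anchor$start
  }
  if (lo >= hi) {
    warning("empty predicted interval (fragment length <= read length?); ",
            "anchor discarded", call. = FALSE)
    return(NULL)
  }
  list(chrom = anchor$chrom, lo = lo, hi = hi)
}

#' Classify a discordant pair into an anchor read
#'
#' Given a valid discordant pair, returns the anchor-read record when one
#' read maps uniquely (not repetitive, `mapq >= mapq_min`) to a non-TE
#' location and its mate overlaps at least one annotated TE at its primary
#' placement or any alternative-hit placement. The mapping-quality filter
#' applies to the anchor only.
#'
#' @param pair Two-row alignment table.
#' @param te A `te_index`.
#' @param stats A [library_stats()] object.
#' @param params A [tei_params()] list (uses `mapq_min` and `s_factor`).
#' @return A list with elements `anchor` (one-row table), `te_hits`
#'   (character vector of TE names hit by the mate) and `interval`
#'   (predicted insertion interval), or `NULL`.
#' @export
classify_pair <- function(pair, te, stats, params = tei_params()) {
  stopifnot(nrow(pair) == 2L)
  if (!is_valid_discordant(pair, stats)) return(NULL)
  for (i in 1:2) {
    a <- pair[i, , drop = FALSE]
    m <- pair[3L - i, , drop = FALSE]
    if (is_repetitive(a) || a$mapq < params$mapq_min) next
    if (overlaps_te(a$chrom, a$start, a$end, te)) next
    placements <- data.frame(chrom = m$chrom, start = m$start, end = m$end)
    alt <- parse_xa(m$xa)
    if (nrow(alt)) {
      placements <- rbind(placements, alt[, c("chrom", "start", "end")])
    }
    hits <- unique(unlist(te_hits_for(placements$chrom, placements$start,
                                      placements$end, te)))
    if (length(hits) == 0L) next
    ivl <- predicted_interval(a, stats, params$s_factor)
    if (is.null(ivl)) next
    return(list(anchor = a, te_hits = sort(hits), interval = ivl))
  }
  NULL
}

# vectorised pipeline step ----------------------------------------------

## Extract all anchor reads from an alignment table. Returns a data.frame
## with columns: qname, chrom, start, end, strand, mapq, ilo, ihi and a
## list-column te_hits.
find_anchor_reads <- function(aln, te, stats, params = tei_params()) {
  empty <- data.frame(qname = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      ilo = numeric(0), ihi = numeric(0))
  empty$te_hits <- list()
  cand <- which(!aln$proper & !is.na(aln$mchrom))
  if (length(cand) < 2L) return(empty)

  ## pair up primary records by read name
  sp <- split(cand, aln$qname[cand])
  sp <- sp[lengths(sp) == 2L]
  if (length(sp) == 0L) return(empty)
  i1 <- vapply(sp, `[`, 0L, 1L)
  i2 <- vapply(sp, `[`, 0L, 2L)

  valid <- (aln$chrom[i1] != aln$chrom[i2]) |
    (abs(aln$start[i1] - aln$start[i2]) > 2 * stats$fragment_mean)
  i1 <- i1[valid]; i2 <- i2[valid]
  if (length(i1) == 0L) return(empty)

  ## evaluate both role assignments (anchor, mate)
  a_idx <- c(i1, i2)
  m_idx <- c(i2, i1)
  repetitive <- aln$mapq[a_idx] == 0L |
    (!is.na(aln$xa[a_idx]) & nzchar(aln$xa[a_idx]))
  ok <- !repetitive & aln$mapq[a_idx] >= params$mapq_min
  if (any(ok)) {
    ok[ok] <- !overlaps_te(aln$chrom[a_idx[ok]], aln$start[a_idx[ok]],
                           aln$end[a_idx[ok]], te)
  }
  a_idx <- a_idx[ok]; m_idx <- m_idx[ok]
  if (length(a_idx) == 0L) return(empty)

  ## mate TE hits over primary + alternative placements
  prim <- te_hits_for(aln$chrom[m_idx], aln$start[m_idx], aln$end[m_idx], te)
  alt <- parse_xa(aln$xa[m_idx])
  if (nrow(alt)) {
    alt_hits <- te_hits_for(alt$chrom, alt$start, alt$end, te)
    by_read <- split(unlist(alt_hits, use.names = FALSE),
                     rep(alt$idx, lengths(alt_hits)))
    for (k in names(by_read)) {
      ki <- as.integer(k)
      prim[[ki]] <- c(prim[[ki]], by_read[[k]])
    }
  }
  te_hits <- lapply(prim, function(h) sort(unique(h)))
  keep <- lengths(te_hits) > 0L
  a_idx <- a_idx[keep]
  te_hits <- te_hits[keep]
  if (length(a_idx) == 0L) return(empty)

  reach <- stats$fragment_mean + params$s_factor * stats$fragment_sd
  fwd <- aln$strand[a_idx] == "+"
  ilo <- ifelse(fwd, aln$end[a_idx], aln$end[a_idx] - reach)
  ihi <- ifelse(fwd, aln$start[a_idx] + reach, aln$start[a_idx])
  good <- ilo < ihi
  if (!all(good)) {
    warning(sum(!good), " anchor(s) with empty predicted interval discarded",
            call. = FALSE)
  }
  out <- data.frame(qname = aln$qname[a_idx], chrom = aln$chrom[a_idx],
                    start = aln$start[a_idx], end = aln$end[a_idx],
                    strand = aln$strand[a_idx], mapq = aln$mapq[a_idx],
                    ilo = ilo, ihi = ihi, stringsAsFactors = FALSE)
  out$te_hits <- te_hits
  out <- out[good, , drop = FALSE]
  rownames(out) <- NULL
  out
}
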