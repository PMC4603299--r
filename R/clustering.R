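# Clustering of anchor reads into maximal mutually-overlapping interval
# sets, isolation filtering, and forward/reverse cluster pairing.

new_cluster <- function(anchors, idx, strand) {
  starts <- anchors$start[idx]
  list(chrom = anchors$chrom[idx][1],
       strand = strand,
       idx = idx,
       lo = max(anchors$ilo[idx]),
       hi = min(anchors$ihi[idx]),
       size = length(idx),
       span = max(starts) - min(starts),
       starts = starts,
       ends = anchors$end[idx],
       qnames = anchors$qname[idx],
       te_names = unlist(anchors$te_hits[idx], use.names = FALSE))
}

#' Cluster anchor reads into isolated maximal-overlap sets
#'
#' Enumerates the maximal cliques of the interval-overlap graph of the
#' anchors' predicted insertion intervals by a left-to-right sweep (interval
#' graphs make maximal cliques enumerable in sorted order), then discards
#' every cluster that conflicts with another cluster. Two clusters conflict
#' when they share a member anchor or when their intersection intervals
#' overlap; only conflict-free ("isolated") clusters are returned, so each
#' anchor appears in at most one returned cluster.
#'
#' @param anchors Anchor-read table (see internals; columns `ilo`, `ihi`,
#'   `start`, `end`, `chrom`, `qname`, list-column `te_hits`), all on one
#'   chromosome and strand.
#' @param strand Strand label stored on the resulting clusters.
#' @return List of cluster objects (lists with `chrom`, `strand`, `idx`,
#'   `lo`, `hi`, `size`, `span`, `starts`, `ends`, `qnames`, `te_names`).
#' @export
cluster_anchors <- function(anchors, strand = "+") {
  n <- nrow(anchors)
  if (n == 0L) return(list())
  stopifnot(length(unique(anchors$chrom)) == 1L)

  ## sweep events: position, type (0 = start, 1 = end), anchor id.
  ## Starts sort before ends at equal positions: predicted intervals are
  ## closed, so intervals touching at a point (e.g. a saturated forward and
  ## reverse side meeting exactly at the insertion point) do overlap.
  pos <- c(anchors$ilo, anchors$ihi)
  type <- rep(c(0L, 1L), each = n)
  id <- rep(seq_len(n), 2L)
  o <- order(pos, type)
  pos <- pos[o]; type <- type[o]; id <- id[o]

  active <- logical(n)
  grown <- FALSE
  cliques <- list()
  for (k in seq_along(pos)) {
    if (type[k] == 0L) {
      active[id[k]] <- TRUE
      grown <- TRUE
    } else {
      if (grown) {
        cliques[[length(cliques) + 1L]] <- which(active)
        grown <- FALSE
      }
      active[id[k]] <- FALSE
    }
  }
  clusters <- lapply(cliques, new_cluster, anchors = anchors,
                     strand = strand)
  isolate_clusters(clusters)
}

## Drop every cluster that shares a member with, or whose intersection
## interval overlaps, another cluster.
isolate_clusters <- function(clusters) {
  m <- length(clusters)
  if (m <= 1L) return(clusters)
  bad <- logical(m)

  membership <- data.frame(cl = rep(seq_len(m),
                                    vapply(clusters, function(x)
                                      length(x$idx), 0L)),
                           anchor = unlist(lapply(clusters, `[[`, "idx")))
  dup_anchors <- unique(membership$anchor[duplicated(membership$anchor)])
  if (length(dup_anchors)) {
    bad[unique(membership$cl[membership$anchor %in% dup_anchors])] <- TRUE
  }

  lo <- vapply(clusters, `[[`, 0, "lo")
  hi <- vapply(clusters, `[[`, 0, "hi")
  open <- integer(0)
  for (k in order(lo)) {
    open <- open[hi[open] >= lo[k]]   # closed intervals: touching overlaps
    if (length(open)) {
      bad[open] <- TRUE
      bad[k] <- TRUE
    }
    open <- c(open, k)
  }
  clusters[!bad]
}

#' Pair forward and reverse clusters by interval overlap
#'
#' A forward and a reverse cluster are paired when their intersection
#' intervals overlap. Any cluster participating in more than one candidate
#' pairing is ambiguous, and every cluster it touches is dropped (with a
#' warning): specificity is favoured over rescuing ambiguous constellations.
#'
#' @param fwd,rev Lists of clusters from [cluster_anchors()] on the same
#'   chromosome.
#' @return List of cluster-pair objects: lists with `fwd`, `rev`, `chrom`.
#' @export
pair_clusters <- function(fwd, rev) {
  if (length(fwd) == 0L || length(rev) == 0L) return(list())
  flo <- vapply(fwd, `[[`, 0, "lo"); fhi <- vapply(fwd, `[[`, 0, "hi")
  rlo <- vapply(rev, `[[`, 0, "lo"); rhi <- vapply(rev, `[[`, 0, "hi")
  ## closed-interval overlap: clusters touching at a point are paired
  ov <- outer(flo, rhi, `<=`) & outer(fhi, rlo, `>=`)
  qf <- row(ov)[ov]
  qr <- col(ov)[ov]
  if (length(qf) == 0L) return(list())
  amb_f <- unique(qf[duplicated(qf)])
  amb_r <- unique(qr[duplicated(qr)])
  drop <- qf %in% amb_f | qr %in% amb_r
  if (any(drop)) {
    warning(sum(drop), " candidate cluster pairing(s) dropped as ambiguous",
            call. = FALSE)
  }
  qf <- qf[!drop]; qr <- qr[!drop]
  mapply(function(i, j) {
    list(fwd = fwd[[i]], rev = rev[[j]], chrom = fwd[[i]]$chrom)
  }, qf, qr, SIMPLIFY = FALSE)
}

#' Insertion-site interval of a cluster pair
#'
#' The insertion site is bounded by the greatest start position of the reads
#' in the forward cluster and the smallest end position of the reads in the
#' reverse cluster. When the read stacks cross (`lo >= hi`), the interval
#' collapses to the single point at the midpoint, with length 0.
#'
#' @param pair A cluster pair from [pair_clusters()].
#' @return Named list `(chrom, lo, hi, interval_length)`.
#' @export
insertion_interval <- function(pair) {
  lo <- max(pair$fwd$starts)
  hi <- min(pair$rev$ends)
  if (lo >= hi) {
    mid <- as.integer(floor((lo + hi) / 2))
    return(list(chrom = pair$chrom, lo = mid, hi = mid,
                interval_length = 0L))
  }
  list(chrom = pair$chrom, lo = lo, hi = hi,
       interval_length = hi - lo)
}

# binning ---------------------------------------------------------------

## Split sorted anchors (both strands merged) into chunks at "quiet"
## points: a split between consecutive anchors is allowed only when no
## predicted interval spans it, so per-chunk clustering and pairing equal
## the single-pass result. Returns a list of index vectors into `anchors`.
chunk_anchor_indices <- function(anchors, bin_size) {
  n <- nrow(anchors)
  if (n == 0L) return(list())
  o <- order(anchors$ilo)
  lo <- anchors$ilo[o]
  hi <- anchors$ihi[o]
  runmax <- cummax(hi)
  ## split allowed before position i (i >= 2) when no (closed) interval
  ## reaches it
  allowed <- c(FALSE, runmax[-n] < lo[-1])
  edges <- integer(0)
  next_edge <- lo[1] + bin_size
  for (i in seq_len(n)[-1]) {
    if (lo[i] >= next_edge && allowed[i]) {
      edges <- c(edges, i)
      next_edge <- lo[i] + bin_size
    }
  }
  bounds <- c(1L, edges, n + 1L)
  lapply(seq_len(length(bounds) - 1L), function(k) {
    o[bounds[k]:(bounds[k + 1L] - 1L)]
  })
}
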