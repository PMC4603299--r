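# Per-call metrics, library-derived default cutoffs, and filtering.

#' Filter configuration for insertion calls
#'
#' Min/max bounds for the five call metrics. All comparisons are strict
#' (`min < value < max`). `require_consistent_te` additionally demands that
#' the forward and reverse clusters agree on the inserted element; it is
#' computed and reported for every call but not enforced by default.
#'
#' @param cluster_size_min,cluster_size_max Bounds on the number of reads in
#'   each of the forward and reverse clusters.
#' @param span_min,span_max Bounds (bp) on each cluster's span (max - min of
#'   member start positions; 0 means the reads are stacked).
#' @param interval_len_min,interval_len_max Bounds (bp) on the insertion
#'   interval length.
#' @param clipped_support_min,clipped_support_max Bounds on the number of
#'   clipped reads supporting the breakpoint.
#' @param require_consistent_te Logical (default `FALSE`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(cluster_size_min, cluster_size_max, span_min,
                          span_max, interval_len_min, interval_len_max,
                          clipped_support_min, clipped_support_max,
                          require_consistent_te = FALSE) {
  x <- list(cluster_size_min = cluster_size_min,
            cluster_size_max = cluster_size_max,
            span_min = span_min, span_max = span_max,
            interval_len_min = interval_len_min,
            interval_len_max = interval_len_max,
            clipped_support_min = clipped_support_min,
            clipped_support_max = clipped_support_max,
            require_consistent_te = isTRUE(require_consistent_te))
  for (pre in c("cluster_size", "span", "interval_len", "clipped_support")) {
    lo <- x[[paste0(pre, "_min")]]
    hi <- x[[paste0(pre, "_max")]]
    if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
      stop("filter config: need ", pre, "_min < ", pre, "_max",
           call. = FALSE)
    }
    if (hi <= 0) stop("filter config: ", pre, "_max must be > 0",
                      call. = FALSE)
  }
  structure(x, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  f <- function(v) format(v, digits = 6)
  cat("filter cutoffs (strict bounds):\n")
  cat(sprintf("  %s < cluster_size < %s (each cluster)\n",
              f(x$cluster_size_min), f(x$cluster_size_max)))
  cat(sprintf("  %s < span < %s (each cluster)\n", f(x$span_min),
              f(x$span_max)))
  cat(sprintf("  %s < interval_length < %s\n", f(x$interval_len_min),
              f(x$interval_len_max)))
  cat(sprintf("  %s < clipped_support < %s\n", f(x$clipped_support_min),
              f(x$clipped_support_max)))
  cat(sprintf("  require_consistent_te: %s\n", x$require_consistent_te))
  invisible(x)
}

#' Default filter cutoffs from library statistics and coverage
#'
#' Generates the library-derived bounds:
#' `2 < cluster_size < 5 * coverage`, `2 < span < fragment_mean`,
#' `read_len_mean < interval_length <
#'  2 * (fragment_mean + 2 * fragment_sd - (read_len_mean - read_len_sd))`,
#' and `2 < clipped_support < 5 * coverage`. Cluster-size and span bounds
#' apply to the forward and reverse clusters separately.
#'
#' @param stats A [library_stats()] object.
#' @param coverage Fold-coverage of the sample (> 0).
#' @return A [filter_config()].
#' @export
default_cutoffs <- function(stats, coverage) {
  validate_library_stats(stats)
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  if (5 * coverage <= 3) {
    stop("coverage too low to derive cluster-size cutoffs ",
         "(5 * coverage <= 3); supply a manual filter config",
         call. = FALSE)
  }
  upper <- 2 * (stats$fragment_mean + 2 * stats$fragment_sd -
                  (stats$read_len_mean - stats$read_len_sd))
  filter_config(cluster_size_min = 2, cluster_size_max = 5 * coverage,
                span_min = 2, span_max = stats$fragment_mean,
                interval_len_min = stats$read_len_mean,
                interval_len_max = upper,
                clipped_support_min = 2,
                clipped_support_max = 5 * coverage,
                require_consistent_te = FALSE)
}

#' Metrics of a cluster pair
#'
#' Computes the five filter metrics of a call: forward/reverse cluster
#' sizes, forward/reverse spans, insertion interval length, clipped
#' support, and TE consistency.
#'
#' @param pair A cluster pair from [pair_clusters()].
#' @param clipped_support Number of clipped reads supporting the breakpoint
#'   (0 when no breakpoint was found).
#' @return Named list of metrics.
#' @export
compute_metrics <- function(pair, clipped_support = 0L) {
  ivl <- insertion_interval(pair)
  id <- annotate_te_identity(pair)
  list(fwd_size = pair$fwd$size, rev_size = pair$rev$size,
       fwd_span = pair$fwd$span, rev_span = pair$rev$span,
       interval_length = ivl$interval_length,
       clipped_support = as.integer(clipped_support),
       consistent_te = id$consistent_te)
}

#' Apply filter cutoffs to insertion calls
#'
#' A call passes when both cluster sizes, both spans, the interval length
#' and the clipped support lie strictly inside their bounds and, if
#' required, the TE identity is consistent between strands. Failing calls
#' record the first violated criterion in `filter_status`
#' (`"fail:<criterion>"`). Idempotent: re-filtering a filtered set with the
#' same config does not change it.
#'
#' @param calls A `tei_calls` data.frame (see [tei_scan()]).
#' @param config A [filter_config()].
#' @return `calls` with the `filter_status` column set.
#' @export
apply_filter <- function(calls, config) {
  n <- nrow(calls)
  status <- rep("pass", n)
  inside <- function(x, lo, hi) !is.na(x) & x > lo & x < hi
  checks <- list(
    cluster_size = inside(calls$fwd_size, config$cluster_size_min,
                          config$cluster_size_max) &
      inside(calls$rev_size, config$cluster_size_min,
             config$cluster_size_max),
    span = inside(calls$fwd_span, config$span_min, config$span_max) &
      inside(calls$rev_span, config$span_min, config$span_max),
    interval_length = inside(calls$interval_length, config$interval_len_min,
                             config$interval_len_max),
    clipped_support = inside(calls$clipped_support,
                             config$clipped_support_min,
                             config$clipped_support_max))
  if (config$require_consistent_te) {
    checks$consistent_te <- !is.na(calls$consistent_te) & calls$consistent_te
  }
  for (crit in rev(names(checks))) {
    status[!checks[[crit]]] <- paste0("fail:", crit)
  }
  calls$filter_status <- status
  calls
}
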