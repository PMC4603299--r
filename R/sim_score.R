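# Scoring of predicted insertions against a simulation truth set.

## allele-fraction class of a zygosity estimate: homozygous when >= 0.75,
## otherwise the nearest of the sub-homozygous classes present in the
## truth design (heterozygous 0.5, low cell fraction 0.25). A two-allele
## simulation is classified hom-vs-het only; the lcf class exists only in
## the tumor design.
classify_af <- function(z, classes = c("hom", "het", "lcf")) {
  targets <- c(het = 0.5, lcf = 0.25)
  targets <- targets[names(targets) %in% classes]
  if (length(targets) == 0L) targets <- c(het = 0.5)
  vapply(z, function(zi) {
    if (is.na(zi)) return(NA_character_)
    if (zi >= 0.75 && "hom" %in% classes) return("hom")
    names(targets)[which.min(abs(zi - targets))]
  }, character(1))
}

#' Score predicted insertions against the simulation truth
#'
#' Matches calls to truth records one-to-one by greedy smallest-distance
#' matching: a call whose position (breakpoint, or interval midpoint when
#' no breakpoint was found) lies within `pad` bp of a truth position is a
#' true positive. Reports positive predictive value, sensitivity,
#' breakpoint errors, zygosity-classification accuracy and per-class
#' detection rates.
#'
#' @param calls A `tei_calls` data.frame (typically the filtered set).
#' @param truth Truth data.frame from [plant_insertions()] (`$truth`).
#' @param pad Matching padding in bp (default 20).
#' @return An object of class `tei_score`: list with `tp`, `fp`, `fn`,
#'   `ppv`, `sensitivity`, `zygosity_accuracy` (all percentages),
#'   `breakpoint_error` (per-TP absolute distances), `by_class`
#'   (per-truth-class detection), and `matches` (per-TP detail table).
#' @export
score_predictions <- function(calls, truth, pad = 20) {
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  pos <- ifelse(!is.na(calls$breakpoint), calls$breakpoint,
                floor((calls$lo + calls$hi) / 2))
  cand <- NULL
  if (n_calls > 0 && n_truth > 0) {
    cand <- do.call(rbind, lapply(seq_len(n_truth), function(j) {
      d <- abs(pos - truth$position[j])
      i <- which(calls$chrom == truth$chrom[j] & d <= pad)
      if (length(i) == 0L) return(NULL)
      data.frame(call = i, truth = j, dist = d[i])
    }))
  }
  used_call <- logical(n_calls); used_truth <- logical(n_truth)
  matches <- list()
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$dist, cand$truth, cand$call), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand$call[k]; j <- cand$truth[k]
      if (used_call[i] || used_truth[j]) next
      used_call[i] <- TRUE; used_truth[j] <- TRUE
      matches[[length(matches) + 1L]] <- data.frame(
        call = i, truth = j, dist = cand$dist[k],
        chrom = truth$chrom[j], position = truth$position[j],
        true_af = truth$true_af[j], true_class = truth$class[j],
        zygosity = calls$zygosity[i],
        pred_class = classify_af(calls$zygosity[i],
                                 classes = unique(truth$class)),
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(call = integer(0), truth = integer(0), dist = numeric(0),
               chrom = character(0), position = numeric(0),
               true_af = numeric(0), true_class = character(0),
               zygosity = numeric(0), pred_class = character(0))
  tp <- nrow(matches)
  fp <- n_calls - tp
  fn <- n_truth - tp
  by_class <- do.call(rbind, lapply(unique(truth$class), function(cl) {
    n <- sum(truth$class == cl)
    det <- sum(matches$true_class == cl)
    data.frame(class = cl, n = n, detected = det,
               pct_detected = 100 * det / n)
  }))
  zacc <- if (tp > 0) {
    100 * mean(!is.na(matches$pred_class) &
                 matches$pred_class == matches$true_class)
  } else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    zygosity_accuracy = zacc,
    breakpoint_error = matches$dist,
    by_class = by_class,
    matches = matches,
    pad = pad), class = "tei_score")
}

#' @export
print.tei_score <- function(x, ...) {
  cat(sprintf("TEI scoring (pad %d bp): TP %d, FP %d, FN %d\n", x$pad,
              x$tp, x$fp, x$fn))
  cat(sprintf("  PPV %.2f%%, sensitivity %.2f%%, zygosity accuracy %s\n",
              x$ppv, x$sensitivity,
              ifelse(is.na(x$zygosity_accuracy), "NA",
                     sprintf("%.2f%%", x$zygosity_accuracy))))
  if (length(x$breakpoint_error)) {
    cat(sprintf("  breakpoint error: median %.1f bp, max %.0f bp\n",
                stats::median(x$breakpoint_error),
                max(x$breakpoint_error)))
  }
  if (!is.null(x$by_class) && nrow(x$by_class)) {
    for (i in seq_len(nrow(x$by_class))) {
      cat(sprintf("  %s: %d/%d detected (%.2f%%)\n",
                  x$by_class$class[i], x$by_class$detected[i],
                  x$by_class$n[i], x$by_class$pct_detected[i]))
    }
  }
  invisible(x)
}
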