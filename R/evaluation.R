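# ---- confusion counts and biometric metrics ----

#' Confusion counts over a comparison set
#'
#' @param decisions logical vector: `TRUE` = declared match.
#' @param labels character vector, `"genuine"` (should match) or
#'   `"impostor"` (should not).
#' @return named list of class `confusion_counts` with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(decisions, labels) {
  if (length(decisions) != length(labels)) {
    stop("decisions and labels differ in length")
  }
  stopifnot(all(labels %in% c("genuine", "impostor")))
  g <- labels == "genuine"
  structure(list(tp = sum(g & decisions), fp = sum(!g & decisions),
                 tn = sum(!g & !decisions), fn = sum(g & !decisions)),
            class = "confusion_counts")
}

#' Verification metrics from confusion counts
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN); F1 = harmonic mean of the
#' two; FMR = FP/(FP+TN) (impostors accepted); FNMR = FN/(FN+TP) (genuines
#' rejected). All returned as fractions in `[0, 1]`; metrics with a zero
#' denominator are `NA` (undefined), never silently 0.
#'
#' `literal_recall = TRUE` computes recall as TP/(TP+TN) instead — a
#' formula that circulates in some write-ups of these metrics but
#' contradicts the accepted definition; it is provided only for literal
#' reproduction and is never a sensible default.
#'
#' @param c a [confusion()] result.
#' @param literal_recall use the TP/(TP+TN) variant.
#' @return named list of class `metric_report` with `precision`, `recall`,
#'   `f1`, `fmr`, `fnmr`.
#' @export
metrics <- function(c, literal_recall = FALSE) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(c$tp, c$tp + c$fp)
  recall <- if (literal_recall) safe_div(c$tp, c$tp + c$tn)
            else safe_div(c$tp, c$tp + c$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(precision = precision, recall = recall, f1 = f1,
                 fmr = safe_div(c$fp, c$fp + c$tn),
                 fnmr = safe_div(c$fn, c$fn + c$tp)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undef" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("<metric_report> precision %s, recall %s, F1 %s, FMR %s, FNMR %s\n",
              pct(x$precision), pct(x$recall), pct(x$f1), pct(x$fmr),
              pct(x$fnmr)))
  invisible(x)
}

# ---- FMR/FNMR sweep over the decision threshold ----

#' FMR/FNMR curves and equal error rate over the TMC threshold
#'
#' For each threshold `t` on a half-integer grid spanning
#' `[min - 1, max + 1]` of the observed matched counts, a comparison is a
#' declared match iff its count >= t; so `fnmr(t)` is the fraction of
#' genuine counts below `t` and `fmr(t)` the fraction of impostor counts at
#' or above `t`. The equal error rate is read off where the two
#' piecewise-linear interpolated curves cross, giving a real-valued
#' threshold (the operating threshold itself must be an integer in
#' deployment).
#'
#' @param genuine_counts,impostor_counts integer vectors of matched-minutiae
#'   counts.
#' @return object of class `sweep_curve`: list with `thresholds`, `fmr`,
#'   `fnmr` (step-curve samples), `eer` and `eer_threshold`.
#' @export
sweep_tmc <- function(genuine_counts, impostor_counts) {
  stopifnot(length(genuine_counts) > 0, length(impostor_counts) > 0)
  all_c <- c(genuine_counts, impostor_counts)
  thr <- seq(min(all_c) - 1, max(all_c) + 1, by = 0.5)
  fnmr <- vapply(thr, function(t) mean(genuine_counts < t), numeric(1))
  fmr <- vapply(thr, function(t) mean(impostor_counts >= t), numeric(1))
  d <- fmr - fnmr          # non-increasing: starts >= 0, ends <= 0
  i <- which(d <= 0)[1]
  if (is.na(i)) {          # degenerate: curves never cross on the grid
    i <- length(thr); frac <- 0
  } else if (i == 1 || d[i] == 0) {
    frac <- 0
  } else {
    frac <- d[i - 1] / (d[i - 1] - d[i])
    i <- i - 1
  }
  eer_threshold <- thr[i] + frac * 0.5
  eer <- fnmr[i] + frac * (fnmr[min(i + 1, length(thr))] - fnmr[i])
  structure(list(thresholds = thr, fmr = fmr, fnmr = fnmr,
                 eer = eer, eer_threshold = eer_threshold),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("<sweep_curve> %d thresholds in [%g, %g], EER %.4f%% at TMC %.2f\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              100 * x$eer, x$eer_threshold))
  invisible(x)
}
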