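# MSE-threshold classifier of perceived fatigue.
#
# Within one medium, the mean of the participants' averaged MSE values is
# the cluster's decision boundary.  Higher complexity is expected to go with
# LESS fatigue, so the positive class is "not fatigued": averaged MSE above
# the boundary predicts a fatigue self-report <= fatigue_cut.  Note this
# inverts the colloquial reading of TP — a true positive is a correctly
# predicted non-fatigued participant.

#' Decision boundary of an MSE cluster
#'
#' The arithmetic mean of a medium's participant-averaged MSE values.
#'
#' @param averaged_mses non-empty numeric vector of finite values.
#' @return The threshold (scalar mean).
#' @export
decision_boundary <- function(averaged_mses) {
  if (length(averaged_mses) == 0) stop_invalid("averaged_mses must be non-empty")
  check_finite(averaged_mses, "averaged_mses")
  mean(averaged_mses)
}

#' Classify one session against a decision boundary
#'
#' Applies the threshold rule: with "above" meaning strictly greater than
#' the boundary (a value exactly on the boundary counts as below), the
#' outcome is
#' \itemize{
#'   \item TP: above the boundary and fatigue <= `fatigue_cut`
#'   \item TN: below the boundary and fatigue >  `fatigue_cut`
#'   \item FP: above the boundary and fatigue >  `fatigue_cut`
#'   \item FN: below the boundary and fatigue <= `fatigue_cut`
#' }
#'
#' @param avg_mse the session's averaged MSE (finite scalar).
#' @param boundary decision threshold.
#' @param fatigue integer fatigue self-report in 1..8 (must be present;
#'   sessions without a self-report are excluded upstream).
#' @param fatigue_cut fatigue binarization threshold (default 4.0).
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
classify_session <- function(avg_mse, boundary, fatigue, fatigue_cut = 4.0) {
  if (!is.finite(avg_mse)) stop_invalid("avg_mse must be finite")
  if (is.na(fatigue) || fatigue < 1 || fatigue > 8)
    stop_invalid("fatigue must be present and in 1..8")
  above <- avg_mse > boundary
  not_fatigued <- fatigue <= fatigue_cut
  if (above && not_fatigued) "TP"
  else if (!above && !not_fatigued) "TN"
  else if (above) "FP"
  else "FN"
}

#' Confusion-matrix metrics from raw counts
#'
#' Computes accuracy, precision, recall and F1 from TP/TN/FP/FN counts using
#' exact rational arithmetic; values are only rounded for display.  Metrics
#' with a zero denominator are returned as `NA` and flagged in `undefined`,
#' never silently set to 0.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return A list with the counts, `accuracy` (proportion), `accuracy_pct`,
#'   `precision`, `recall`, `f1`, and `undefined` (character vector of
#'   metric names with zero denominators).
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop_invalid("at least one classified session is required")
  undefined <- character(0)
  accuracy <- (tp + tn) / total
  precision <- if (tp + fp > 0) tp / (tp + fp) else { undefined <- c(undefined, "precision"); NA_real_ }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "recall"); NA_real_ }
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    undefined <- c(undefined, "f1"); NA_real_
  }
  list(counts = as.list(counts), total = total,
       accuracy = accuracy, accuracy_pct = 100 * accuracy,
       precision = precision, recall = recall, f1 = f1,
       undefined = undefined)
}

#' Evaluate the MSE-threshold classifier for one medium
#'
#' Computes the medium's decision boundary from the participants' averaged
#' MSE values, classifies every session with a fatigue self-report, and
#' reports confusion counts and metrics.  The boundary is computed on the
#' same sessions it classifies (in-sample, by design of the procedure);
#' sessions with a missing fatigue score are excluded before the boundary is
#' taken, mirroring their exclusion from the prediction analysis.
#'
#' @param avg_mses numeric vector of participant-averaged MSE values.
#' @param fatigue integer vector (same length) of fatigue self-reports,
#'   `NA` for missing.
#' @param medium medium label for the report.
#' @param fatigue_cut fatigue binarization threshold (default 4.0).
#' @return An object of class `classifier_report`: medium, boundary, counts,
#'   metrics, `chance_level` (50), and the number of sessions used/excluded.
#' @export
evaluate_medium <- function(avg_mses, fatigue, medium = NA_character_,
                            fatigue_cut = 4.0) {
  if (length(avg_mses) != length(fatigue))
    stop_invalid("avg_mses and fatigue must have equal length")
  keep <- !is.na(fatigue) & is.finite(avg_mses)
  n_excluded <- sum(!keep)
  avg_mses <- avg_mses[keep]; fatigue <- fatigue[keep]
  if (length(avg_mses) == 0)
    stop_invalid("no sessions with a fatigue self-report in medium '%s'", medium)
  boundary <- decision_boundary(avg_mses)
  labels <- mapply(classify_session, avg_mses, fatigue,
                   MoreArgs = list(boundary = boundary, fatigue_cut = fatigue_cut))
  tab <- table(factor(labels, levels = c("TP", "TN", "FP", "FN")))
  metrics <- metrics_from_counts(tab[["TP"]], tab[["TN"]], tab[["FP"]], tab[["FN"]])
  structure(c(list(medium = medium, boundary = boundary,
                   fatigue_cut = fatigue_cut, in_sample = TRUE,
                   chance_level = 50.0, n_excluded = n_excluded),
              metrics),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undef", sprintf("%.2f", v))
  cat(sprintf("Fatigue classifier, medium %s (in-sample boundary %.4f, fatigue cut %.1f)\n",
              x$medium, x$boundary, x$fatigue_cut))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d   (n = %d, %d excluded, chance %.1f%%)\n",
              x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn,
              x$total, x$n_excluded, x$chance_level))
  cat(sprintf("  accuracy %.2f%%  precision %s  recall %s  F1 %s\n",
              x$accuracy_pct, fmt(x$precision), fmt(x$recall), fmt(x$f1)))
  if (length(x$undefined))
    cat("  undefined metrics:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
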