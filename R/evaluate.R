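#' Evaluate DCR predictions against reported human outcomes
#'
#' Cross-tabulates the safe/not-safe DCR classification with the reported
#' outcome of each scenario. A reported positive outcome (AChE inhibition
#' with toxic signs) predicted \code{not_safe} is a true positive; a reported
#' negative outcome predicted \code{safe} is a true negative; a negative
#' outcome flagged \code{not_safe} is a false positive, and a positive
#' outcome passed as \code{safe} is a false negative -- the failure mode a
#' conservative screen must avoid. Scenarios with unknown (unreported)
#' outcomes are counted separately and never enter the confusion counts.
#'
#' @param records a \code{"dcr_table"} (or data frame) with columns
#'   \code{predicted_label}, \code{reported_outcome}, \code{compound},
#'   \code{dose_mg_per_kg} and \code{dcr}.
#' @return An object of class \code{"dcr_evaluation"}: list with
#'   \code{n_scenarios}, \code{n_positive}, \code{n_negative},
#'   \code{n_unknown}, \code{tp}, \code{tn}, \code{fp}, \code{fn},
#'   \code{cutoff} and \code{misclassified} (data frame sorted by DCR,
#'   largest first).
#' @export
#' @examples
#' fx <- op_fixture()
#' tab <- dcr_pipeline(fx$scenarios, fx$compounds, fx$comparator, signif = 2)
#' evaluate_dcr(tab)
evaluate_dcr <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must contain at least one scenario", call. = FALSE)
  }
  need <- c("predicted_label", "reported_outcome", "dcr")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  outcome <- records$reported_outcome
  pred <- as.character(records$predicted_label)

  pos <- outcome == "positive"
  neg <- outcome == "negative"
  unsafe <- pred == "not_safe"

  mis <- records[(pos & !unsafe) | (neg & unsafe), , drop = FALSE]
  keep <- intersect(c("compound", "dose_mg_per_kg", "dcr",
                      "reported_outcome", "predicted_label"), names(mis))
  mis <- as.data.frame(mis)[order(-mis$dcr), keep, drop = FALSE]
  rownames(mis) <- NULL

  out <- list(
    n_scenarios = nrow(records),
    n_positive = sum(pos),
    n_negative = sum(neg),
    n_unknown = sum(outcome == "unknown"),
    tp = sum(pos & unsafe),
    fn = sum(pos & !unsafe),
    tn = sum(neg & !unsafe),
    fp = sum(neg & unsafe),
    cutoff = if (!is.null(records$cutoff)) records$cutoff[1] else NA_real_,
    misclassified = mis
  )
  class(out) <- "dcr_evaluation"
  out
}

#' @export
print.dcr_evaluation <- function(x, ...) {
  cat("DCR prediction evaluation (cutoff ", x$cutoff, ")\n", sep = "")
  cat(sprintf("  %d scenario(s): %d positive, %d negative, %d unknown\n",
              x$n_scenarios, x$n_positive, x$n_negative, x$n_unknown))
  cat(sprintf("  true positives  %3d   false negatives %3d\n", x$tp, x$fn))
  cat(sprintf("  true negatives  %3d   false positives %3d\n", x$tn, x$fp))
  if (nrow(x$misclassified)) {
    cat("  misclassified scenarios (largest DCR first):\n")
    print(x$misclassified, digits = 3)
  } else {
    cat("  no misclassified scenarios\n")
  }
  invisible(x)
}

#' Coerce an evaluation to a one-row data frame
#' @param x a \code{"dcr_evaluation"}.
#' @param ... unused.
#' @export
as.data.frame.dcr_evaluation <- function(x, ...) {
  data.frame(n_scenarios = x$n_scenarios, n_positive = x$n_positive,
             n_negative = x$n_negative, n_unknown = x$n_unknown,
             tp = x$tp, fn = x$fn, tn = x$tn, fp = x$fp, cutoff = x$cutoff)
}

#' Predictions for scenarios with unreported outcomes
#'
#' Returns the DCR records whose human outcome is unknown, with their
#' predicted labels. These are the application of the approach (screening
#' unevaluated exposures), not part of its evaluation, and are never imputed
#' into the confusion counts.
#'
#' @param records a \code{"dcr_table"} (or data frame) with columns
#'   \code{reported_outcome}, \code{dcr} and \code{predicted_label}.
#' @return Data frame of the unknown-outcome rows (possibly empty).
#' @export
predict_unknowns <- function(records) {
  stopifnot(is.data.frame(records))
  out <- records[records$reported_outcome == "unknown", , drop = FALSE]
  keep <- intersect(c("compound", "dose_mg_per_kg", "cbmax_oxon_uM",
                      "dcr", "predicted_label"), names(out))
  out <- as.data.frame(out)[, keep, drop = FALSE]
  rownames(out) <- NULL
  out
}
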