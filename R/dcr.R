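#' Dose normalisation to body weight
#'
#' Converts an ingested amount to a dose per kilogram body weight. Where a
#' case report gives only the ingested amount, a default adult body weight of
#' 70 kg is assumed regardless of age, sex and ethnicity.
#'
#' @param amount_mg ingested amount (mg), strictly positive.
#' @param body_weight_kg body weight (kg), strictly positive; default 70.
#' @return Dose in mg/kg body weight.
#' @export
#' @examples
#' normalize_dose(15000)        # 214.3 mg/kg at the default 70 kg
normalize_dose <- function(amount_mg, body_weight_kg = 70) {
  stop_unless_positive(amount_mg, "amount_mg")
  stop_unless_positive(body_weight_kg, "body_weight_kg")
  amount_mg / body_weight_kg
}

#' Correct a predicted blood oxon concentration
#'
#' Kinetic models for dimethyl organothiophosphates (e.g. fenitrothion,
#' methyl parathion) have been reported to overpredict blood oxon
#' concentrations by about one order of magnitude; raw model predictions for
#' that class are therefore divided by 10 before use. For diethyl
#' organothiophosphates and direct-acting oxons the divisor is 1. The
#' correction applies only to raw model predictions, never to measured blood
#' concentrations.
#'
#' @param cbmax_uM raw predicted maximum blood oxon concentration (uM).
#' @param divisor correction divisor (default 1; 10 for dimethyl
#'   organothiophosphates).
#' @return Corrected concentration in uM.
#' @export
#' @examples
#' correct_cbmax(0.051, divisor = 10)  # 0.0051
correct_cbmax <- function(cbmax_uM, divisor = 1) {
  stop_unless_positive(cbmax_uM, "cbmax_uM")
  stop_unless_positive(divisor, "divisor")
  cbmax_uM / divisor
}

#' Exposure Activity Ratio
#'
#' The EAR of an exposure scenario is the internal exposure concentration
#' divided by the in vitro potency: here the predicted maximum blood oxon
#' concentration over the IC50 of the same oxon for erythrocyte AChE
#' inhibition. Both are concentrations in uM, so the ratio is dimensionless.
#'
#' @param cbmax_uM maximum blood oxon concentration (uM).
#' @param ic50_uM IC50 of the oxon (uM).
#' @return Dimensionless EAR.
#' @export
#' @examples
#' ear(0.015, 0.38)  # ~0.039, chlorpyrifos oxon at its safe exposure level
ear <- function(cbmax_uM, ic50_uM) {
  stop_unless_positive(cbmax_uM, "cbmax_uM")
  stop_unless_positive(ic50_uM, "ic50_uM")
  cbmax_uM / ic50_uM
}

#' Define the comparator exposure
#'
#' The comparator anchors the DCR scale at a known-safe human exposure. Its
#' EAR is defined from in vitro data alone: the benchmark concentration lower
#' confidence limit at 5\% AChE inhibition (BMCL05) over the IC50 of the
#' comparator's active oxon. The ratio is stored unrounded: downstream DCR
#' values are only reproducible against published tables when the full
#' precision is carried.
#'
#' @param bmcl05_uM BMCL05 of the comparator oxon (uM).
#' @param ic50_uM IC50 of the comparator oxon (uM); must exceed
#'   \code{bmcl05_uM}.
#' @param compound comparator compound name; default \code{"chlorpyrifos"},
#'   whose no-observed-adverse-effect level of 2 mg/kg body weight yields a
#'   predicted blood oxon concentration equal to the in vitro BMCL05.
#' @return An object of class \code{"dcr_comparator"}: list with
#'   \code{compound}, \code{bmcl05_uM}, \code{ic50_uM} and the unrounded
#'   \code{ear}.
#' @export
#' @examples
#' dcr_comparator(0.015, 0.38)
dcr_comparator <- function(bmcl05_uM, ic50_uM, compound = "chlorpyrifos") {
  stop_unless_positive(bmcl05_uM, "bmcl05_uM")
  stop_unless_positive(ic50_uM, "ic50_uM")
  if (bmcl05_uM >= ic50_uM) {
    stop("the comparator BMCL05 must lie below its IC50", call. = FALSE)
  }
  structure(list(compound = compound, bmcl05_uM = bmcl05_uM,
                 ic50_uM = ic50_uM, ear = ear(bmcl05_uM, ic50_uM)),
            class = "dcr_comparator")
}

#' @export
print.dcr_comparator <- function(x, digits = 4, ...) {
  cat("DCR comparator:", x$compound, "\n")
  cat("  BMCL05:", x$bmcl05_uM, "uM;  IC50:", x$ic50_uM, "uM\n")
  cat("  EAR_comparator:", signif(x$ear, digits), "(carried unrounded)\n")
  invisible(x)
}

#' Dietary Comparator Ratio
#'
#' The DCR of an exposure scenario is its EAR divided by the EAR of the
#' comparator's safe exposure. A DCR at or below 1 indicates that the
#' scenario is no closer to bioactive internal concentrations than a human
#' exposure known to be safe.
#'
#' @param ear_test EAR of the test scenario (dimensionless, positive).
#' @param comparator a [dcr_comparator()] object, or the numeric
#'   EAR_comparator itself.
#' @return Dimensionless DCR.
#' @export
#' @examples
#' cmp <- dcr_comparator(0.015, 0.38)
#' dcr(10.75, cmp)  # ~272
dcr <- function(ear_test, comparator) {
  stop_unless_positive(ear_test, "ear_test")
  e <- if (inherits(comparator, "dcr_comparator")) comparator$ear
       else comparator
  stop_unless_positive(e, "comparator EAR")
  ear_test / e
}

#' Classify a DCR value against a safety cutoff
#'
#' Scenarios with DCR less than or equal to the cutoff raise no safety
#' concern (\code{"safe"}); adverse effects cannot be ruled out above it
#' (\code{"not_safe"}). The default cutoff is 1; a cutoff of 0.1 corresponds
#' to applying a 10-fold uncertainty factor for human variability.
#'
#' @param dcr_value vector of positive DCR values.
#' @param cutoff positive classification cutoff, default 1.
#' @return Factor with levels \code{"safe"}, \code{"not_safe"}.
#' @export
#' @examples
#' classify_dcr(c(0.04, 1, 38))
classify_dcr <- function(dcr_value, cutoff = 1) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0) {
    stop("`cutoff` must be a single positive number", call. = FALSE)
  }
  if (length(dcr_value)) stop_unless_positive(dcr_value, "dcr_value")
  factor(ifelse(dcr_value <= cutoff, "safe", "not_safe"),
         levels = c("safe", "not_safe"))
}

#' Run the DCR pipeline over a table of exposure scenarios
#'
#' For each scenario: resolve the compound record, derive the dose in mg/kg
#' from an ingested amount where needed (metadata only; the internal
#' concentration is an input), apply the blood-concentration correction to
#' raw model predictions, compute the EAR and DCR, and classify against the
#' cutoff. Output rows are in input order.
#'
#' @param scenarios data frame with columns \code{compound},
#'   \code{cbmax_oxon_uM} and \code{reported_outcome}
#'   (\code{"positive"}/\code{"negative"}/\code{"unknown"}); optional columns
#'   \code{dose_mg_per_kg}, \code{ingested_amount_mg}, \code{body_weight_kg}
#'   (default 70), \code{cbmax_is_corrected} (default \code{TRUE}: the stored
#'   value already includes any class-specific correction) and
#'   \code{source_note}.
#' @param compounds data frame with columns \code{name}, \code{op_class},
#'   \code{active_species}, \code{ic50_uM} and \code{correction_divisor}.
#' @param comparator a [dcr_comparator()] object.
#' @param cutoff classification cutoff, default 1.
#' @param signif optional integer: round the DCR (and EAR) to this many
#'   significant digits before classification. Use when the scenario table
#'   stores inputs at limited printed precision (e.g. 2 significant figures),
#'   so that classification at the DCR = 1 boundary does not over-read
#'   precision the inputs do not carry; leave \code{NULL} (exact) for
#'   full-precision data.
#' @return A data frame of class \code{"dcr_table"} with the scenario
#'   columns plus \code{ic50_uM}, \code{ear_test}, \code{dcr},
#'   \code{predicted_label} and \code{cutoff}; the comparator is attached as
#'   attribute \code{"comparator"}.
#' @export
#' @examples
#' fx <- op_fixture()
#' head(dcr_pipeline(fx$scenarios, fx$compounds, fx$comparator, signif = 2))
dcr_pipeline <- function(scenarios, compounds, comparator, cutoff = 1,
                         signif = NULL) {
  stopifnot(is.data.frame(scenarios), is.data.frame(compounds))
  if (!inherits(comparator, "dcr_comparator")) {
    stop("`comparator` must be a dcr_comparator object", call. = FALSE)
  }
  need <- c("compound", "cbmax_oxon_uM", "reported_outcome")
  missing_cols <- setdiff(need, names(scenarios))
  if (length(missing_cols)) {
    stop("scenario table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(scenarios) == 0L) {
    out <- scenarios
    out$ic50_uM <- out$ear_test <- out$dcr <- numeric(0)
    out$predicted_label <- factor(character(0),
                                  levels = c("safe", "not_safe"))
    out$cutoff <- numeric(0)
    return(new_dcr_table(out, comparator))
  }
  bad_outcome <- setdiff(unique(scenarios$reported_outcome),
                         c("positive", "negative", "unknown"))
  if (length(bad_outcome)) {
    stop("invalid reported_outcome value(s): ",
         paste(bad_outcome, collapse = ", "), call. = FALSE)
  }

  idx <- match(scenarios$compound, compounds$name)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("scenario row(s) ", paste(bad, collapse = ", "),
         " name compound(s) absent from the compound table: ",
         paste(unique(scenarios$compound[bad]), collapse = ", "),
         call. = FALSE)
  }

  out <- scenarios
  if (is.null(out$body_weight_kg)) out$body_weight_kg <- 70
  out$body_weight_kg[is.na(out$body_weight_kg)] <- 70
  if (is.null(out$dose_mg_per_kg)) out$dose_mg_per_kg <- NA_real_
  if (!is.null(out$ingested_amount_mg)) {
    fill <- is.na(out$dose_mg_per_kg) & !is.na(out$ingested_amount_mg)
    if (any(fill)) {
      out$dose_mg_per_kg[fill] <- normalize_dose(
        out$ingested_amount_mg[fill], out$body_weight_kg[fill])
    }
  }
  if (anyNA(out$dose_mg_per_kg)) {
    stop("scenario row(s) ", paste(which(is.na(out$dose_mg_per_kg)),
                                   collapse = ", "),
         " carry neither a dose nor an ingested amount", call. = FALSE)
  }

  corrected <- if (is.null(out$cbmax_is_corrected)) {
    rep(TRUE, nrow(out))
  } else {
    as.logical(out$cbmax_is_corrected)
  }
  divisor <- ifelse(corrected, 1, compounds$correction_divisor[idx])
  cbmax <- correct_cbmax(out$cbmax_oxon_uM, 1) / divisor

  out$ic50_uM <- compounds$ic50_uM[idx]
  out$ear_test <- ear(cbmax, out$ic50_uM)
  out$dcr <- dcr(out$ear_test, comparator)
  if (!is.null(signif)) {
    out$ear_test <- signif(out$ear_test, signif)
    out$dcr <- signif(out$dcr, signif)
  }
  out$predicted_label <- classify_dcr(out$dcr, cutoff)
  out$cutoff <- cutoff
  new_dcr_table(out, comparator)
}

new_dcr_table <- function(df, comparator) {
  structure(df, comparator = comparator,
            class = c("dcr_table", "data.frame"))
}

#' @export
print.dcr_table <- function(x, ...) {
  cmp <- attr(x, "comparator")
  cat("DCR screening table:", nrow(x), "scenario(s)")
  if (!is.null(cmp)) {
    cat(", comparator ", cmp$compound, " (EAR ", signif(cmp$ear, 4), ")",
        sep = "")
  }
  cat("\n")
  if (nrow(x)) {
    cat("Predicted:", sum(x$predicted_label == "safe"), "safe,",
        sum(x$predicted_label == "not_safe"), "not safe (cutoff",
        x$cutoff[1], ")\n\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}

#' Screen a measured blood concentration
#'
#' Treats a measured blood concentration (e.g. from biomonitoring of
#' environmental exposure) as the maximum blood oxon concentration and
#' returns the full DCR record. No model-correction divisor is applied: the
#' value is measured, not a kinetic-model prediction.
#'
#' @param measured_uM measured blood concentration (uM), positive.
#' @param compound compound name present in \code{compounds}.
#' @param compounds compound table as in [dcr_pipeline()].
#' @param comparator a [dcr_comparator()] object.
#' @param cutoff classification cutoff, default 1.
#' @return A one-row \code{"dcr_table"}.
#' @export
#' @examples
#' fx <- op_fixture()
#' screen_blood(2e-4, "methyl parathion", fx$compounds, fx$comparator)
screen_blood <- function(measured_uM, compound, compounds, comparator,
                         cutoff = 1) {
  stop_unless_positive(measured_uM, "measured_uM")
  if (length(measured_uM) != 1L || length(compound) != 1L) {
    stop("`screen_blood` screens one measurement at a time", call. = FALSE)
  }
  i <- match(compound, compounds$name)
  if (is.na(i)) {
    stop("compound '", compound, "' absent from the compound table",
         call. = FALSE)
  }
  ear_t <- ear(measured_uM, compounds$ic50_uM[i])
  d <- dcr(ear_t, comparator)
  out <- data.frame(
    compound = compound,
    cbmax_oxon_uM = measured_uM,
    reported_outcome = "unknown",
    source_note = "measured blood concentration (no correction applied)",
    ic50_uM = compounds$ic50_uM[i],
    ear_test = ear_t,
    dcr = d,
    predicted_label = classify_dcr(d, cutoff),
    cutoff = cutoff
  )
  new_dcr_table(out, comparator)
}

# shared input guard: finite, numeric, strictly positive (vectorised)
stop_unless_positive <- function(x, label) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) ||
      any(x <= 0)) {
    stop("`", label, "` must be finite and strictly positive", call. = FALSE)
  }
  invisible(x)
}
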