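#' Simulate a replicated in vitro inhibition curve
#'
#' Generates replicate-level AChE inhibition data with the structure of a
#' triplicate in vitro assay: responses on the true 4PL curve plus i.i.d.
#' Gaussian noise in \% activity units. By default eight concentrations are
#' log-spaced over +/- 2.5 decades around the true IC50. The generating
#' parameters are retained as attribute \code{"truth"}, so parameter-recovery
#' checks can compare fitted against true values.
#'
#' @param ic50 true IC50 (uM).
#' @param top,bottom true asymptotes (\% activity); defaults 100 and 0.
#' @param hill true Hill slope; default 1.
#' @param concentrations optional vector of assay concentrations (uM);
#'   default 8 points log-spaced over \code{ic50 * 10^c(-2.5, 2.5)}.
#' @param n_replicates replicates per concentration; default 3.
#' @param noise_sd Gaussian noise standard deviation in \% activity units;
#'   default 3 (of the order of the between-experiment scatter of triplicate
#'   blood assays).
#' @param seed optional integer seed (RNG state restored on exit).
#' @param compound label stored in the output.
#' @return Data frame with columns \code{compound}, \code{concentration_uM},
#'   \code{replicate} and \code{activity_percent}; attribute \code{"truth"}
#'   is a named list of the generating parameters.
#' @export
#' @examples
#' d <- simulate_inhibition_curve(ic50 = 0.38, seed = 7)
#' attr(d, "truth")$ic50
simulate_inhibition_curve <- function(ic50, top = 100, bottom = 0, hill = 1,
                                      concentrations = NULL,
                                      n_replicates = 3L, noise_sd = 3,
                                      seed = NULL,
                                      compound = "synthetic oxon") {
  stop_unless_positive(ic50, "ic50")
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (is.null(concentrations)) {
    concentrations <- ic50 * 10^seq(-2.5, 2.5, length.out = 8)
  }
  stop_unless_positive(concentrations, "concentrations")

  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  conc <- rep(concentrations, each = n_replicates)
  mu <- fourpl_response(conc, top, bottom, log10(ic50), hill)
  out <- data.frame(
    compound = compound,
    concentration_uM = conc,
    replicate = rep(seq_len(n_replicates), times = length(concentrations)),
    activity_percent = mu + stats::rnorm(length(conc), 0, noise_sd)
  )
  attr(out, "truth") <- list(top = top, bottom = bottom, ic50 = ic50,
                             hill = hill, noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate an exposure-scenario table with known ground truth
#'
#' Draws exposure scenarios for the compounds in \code{compounds}: doses are
#' log-uniform over \code{dose_range}, the maximum blood oxon concentration
#' follows a per-compound linear coefficient (uM per mg/kg), optionally with
#' Michaelis-Menten-style saturation at high dose (a stand-in for the
#' saturable kinetics real blood concentrations show, not a kinetic-model
#' claim), and the true outcome label is assigned by thresholding the true
#' DCR at \code{true_cutoff}. Labels are then flipped independently with
#' probability \code{label_noise} to emulate misreported outcomes; the
#' pre-noise truth is kept in column \code{true_outcome}.
#'
#' @param compounds compound table as in [dcr_pipeline()].
#' @param comparator a [dcr_comparator()] used to define the true DCR.
#' @param n_scenarios number of scenarios to draw.
#' @param dose_range length-2 positive vector (mg/kg), log-uniform sampling
#'   range; default \code{c(0.01, 1000)}, spanning volunteer studies through
#'   poisoning cases.
#' @param cbmax_coef named vector of linear coefficients (uM per mg/kg), one
#'   per compound; default \code{ic50_uM / 100} per compound so that doses
#'   span both safe and unsafe true DCR values.
#' @param saturation_dose optional dose scale (mg/kg) at which the
#'   cbmax-dose relation saturates: \code{cbmax = coef * dose / (1 + dose /
#'   saturation_dose)}; \code{NULL} (default) keeps the relation linear.
#' @param true_cutoff DCR threshold defining the true label; default 1.
#' @param label_noise probability in [0, 0.5) of flipping a reported label.
#' @param seed optional integer seed (RNG state restored on exit).
#' @return Scenario data frame as consumed by [dcr_pipeline()], with extra
#'   columns \code{true_dcr} and \code{true_outcome}.
#' @export
#' @examples
#' fx <- op_fixture()
#' s <- simulate_scenarios(fx$compounds, fx$comparator, 20, seed = 1)
#' table(s$reported_outcome)
simulate_scenarios <- function(compounds, comparator, n_scenarios,
                               dose_range = c(0.01, 1000),
                               cbmax_coef = NULL, saturation_dose = NULL,
                               true_cutoff = 1, label_noise = 0,
                               seed = NULL) {
  stopifnot(is.data.frame(compounds), n_scenarios >= 0)
  if (!inherits(comparator, "dcr_comparator")) {
    stop("`comparator` must be a dcr_comparator object", call. = FALSE)
  }
  stop_unless_positive(dose_range, "dose_range")
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("`label_noise` must lie in [0, 0.5)", call. = FALSE)
  }
  if (is.null(cbmax_coef)) {
    cbmax_coef <- stats::setNames(compounds$ic50_uM / 100, compounds$name)
  }
  if (n_scenarios == 0L) {
    out <- data.frame(compound = character(0), dose_mg_per_kg = numeric(0),
                      body_weight_kg = numeric(0),
                      cbmax_oxon_uM = numeric(0),
                      cbmax_is_corrected = logical(0),
                      reported_outcome = character(0),
                      true_dcr = numeric(0), true_outcome = character(0))
    return(out)
  }

  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  cpd <- sample(compounds$name, n_scenarios, replace = TRUE)
  dose <- 10^stats::runif(n_scenarios, log10(dose_range[1]),
                          log10(dose_range[2]))
  coefs <- cbmax_coef[cpd]
  cbmax <- coefs * dose
  if (!is.null(saturation_dose)) {
    stop_unless_positive(saturation_dose, "saturation_dose")
    cbmax <- coefs * dose / (1 + dose / saturation_dose)
  }
  ic50 <- compounds$ic50_uM[match(cpd, compounds$name)]
  true_dcr <- dcr(ear(cbmax, ic50), comparator)
  truth <- ifelse(true_dcr <= true_cutoff, "negative", "positive")
  flip <- stats::runif(n_scenarios) < label_noise
  reported <- ifelse(flip,
                     ifelse(truth == "negative", "positive", "negative"),
                     truth)
  data.frame(
    compound = cpd,
    dose_mg_per_kg = dose,
    body_weight_kg = 70,
    cbmax_oxon_uM = unname(cbmax),
    cbmax_is_corrected = TRUE,
    reported_outcome = reported,
    true_dcr = unname(true_dcr),
    true_outcome = truth
  )
}
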