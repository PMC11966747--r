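#' Benchmark concentration from a fitted curve (closed form)
#'
#' Inverts the fitted four-parameter log-logistic curve at the benchmark
#' response (BMR). The BMR is defined as a fractional decrease in AChE
#' activity relative to the fitted control level (\code{top}): the benchmark
#' concentration (BMC) is the concentration at which the predicted remaining
#' activity equals \code{top * (1 - bmr)}. For \code{top = 100},
#' \code{bottom = 0} and Hill slope \eqn{h} this reduces to
#' \deqn{\mathrm{BMC} = \mathrm{IC_{50}} \cdot
#'   \left(\frac{bmr}{1 - bmr}\right)^{1/h},}
#' e.g. \eqn{0.05263 \cdot \mathrm{IC_{50}}} at the default 5\% BMR with
#' \eqn{h = 1}.
#'
#' @param fit a converged \code{"fourpl"} fit (see [fit_fourpl()]).
#' @param bmr benchmark response as a fraction of inhibition in (0, 1);
#'   default 0.05 (5\% AChE inhibition, a conservative endpoint).
#' @return BMC in uM.
#' @export
#' @examples
#' d <- simulate_inhibition_curve(ic50 = 1, noise_sd = 0, seed = 1)
#' f <- fit_fourpl(activity_percent ~ concentration_uM, d)
#' bmc(f, bmr = 0.05)  # ~0.05263 uM
bmc <- function(fit, bmr = 0.05) {
  if (!inherits(fit, "fourpl")) stop("`fit` must be a fourpl object",
                                     call. = FALSE)
  if (!isTRUE(fit$converged)) {
    stop("cannot derive a BMC from a non-converged fit", call. = FALSE)
  }
  if (!is.numeric(bmr) || length(bmr) != 1L || bmr <= 0 || bmr >= 1) {
    stop("`bmr` must be a single value in (0, 1)", call. = FALSE)
  }
  cf <- coef(fit)
  top <- cf[["top"]]; bottom <- cf[["bottom"]]; hill <- cf[["hill"]]
  # response at the BMC must lie strictly between the asymptotes
  max_bmr <- (top - bottom) / top
  if (top <= 0 || bmr >= max_bmr) {
    stop("BMR of ", bmr, " is not reachable by the fitted curve; the ",
         "attainable range is (0, ", signif(max(max_bmr, 0), 4), ")",
         call. = FALSE)
  }
  u <- top * bmr / (top * (1 - bmr) - bottom)
  unname(10^cf[["log10_ic50"]] * u^(1 / hill))
}

#' Benchmark concentration with bootstrap confidence limits
#'
#' Estimates the BMC for a stated benchmark response together with its lower
#' and upper one-sided confidence limits (BMCL, BMCU) by a parametric
#' bootstrap: the 4PL model is fitted to the data, replicate responses are
#' re-simulated from the fitted curve with Gaussian noise at the residual
#' standard deviation, the model is refitted to each bootstrap sample, and the
#' BMCL/BMCU are the empirical \eqn{1 - level} and \eqn{level} quantiles of
#' the bootstrap BMC distribution. The small fixed designs typical of
#' triplicate in vitro assays make nonparametric case resampling unstable,
#' hence the parametric scheme. Results are bit-reproducible for a given
#' \code{seed}.
#'
#' @param formula,data replicate-level concentration-response data as in
#'   [fit_fourpl()].
#' @param bmr benchmark response (fraction of inhibition), default 0.05.
#' @param level one-sided confidence level in (0.5, 1), default 0.95.
#' @param B number of bootstrap replicates (at least 200), default 1000.
#' @param seed integer seed for the bootstrap RNG (state restored on exit).
#' @param max_fail maximum tolerated fraction of non-converged bootstrap
#'   refits (default 0.2); exceeding it is an error.
#' @param ... passed on to [fit_fourpl()] (e.g. bounds).
#' @return An object of class \code{"bmc_boot"}: list with \code{bmc},
#'   \code{bmcl}, \code{bmcu} (uM), \code{bmr}, \code{level},
#'   \code{model_label}, \code{B}, \code{B_used} (successful refits),
#'   \code{seed}, \code{boot_bmc} (the bootstrap draws) and \code{fit} (the
#'   original \code{"fourpl"} fit). The ordering \code{bmcl <= bmc <= bmcu}
#'   is enforced on every successful run.
#' @export
#' @examples
#' d <- simulate_inhibition_curve(ic50 = 0.38, seed = 1)
#' bmc_bootstrap(activity_percent ~ concentration_uM, d, B = 200, seed = 1)
bmc_bootstrap <- function(formula, data, bmr = 0.05, level = 0.95, B = 1000L,
                          seed = NULL, max_fail = 0.2, ...) {
  if (!is.numeric(level) || level <= 0.5 || level >= 1) {
    stop("`level` must be in (0.5, 1)", call. = FALSE)
  }
  if (!is.numeric(B) || B < 200L) {
    stop("`B` must be at least 200 bootstrap replicates", call. = FALSE)
  }
  fit <- fit_fourpl(formula, data, ...)
  if (fit$trend_warning) {
    stop("data show no decreasing concentration-response trend; ",
         "refusing benchmark concentration analysis on a flat curve",
         call. = FALSE)
  }
  point <- bmc(fit, bmr)  # errors here if the BMR is unreachable

  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  mu <- fit$fitted
  df_boot <- fit$data
  start <- as.list(coef(fit))
  boot <- vapply(seq_len(B), function(i) {
    df_boot$activity <- mu + stats::rnorm(length(mu), 0, fit$sigma)
    refit <- try(suppressWarnings(
      fit_fourpl(activity ~ conc, df_boot, start = start, ...)
    ), silent = TRUE)
    if (inherits(refit, "try-error")) return(NA_real_)
    b <- try(bmc(refit, bmr), silent = TRUE)
    if (inherits(b, "try-error")) NA_real_ else b
  }, numeric(1))

  ok <- is.finite(boot)
  if (mean(!ok) > max_fail) {
    stop("bootstrap failure rate ", signif(mean(!ok), 3),
         " exceeds the tolerated ", max_fail, call. = FALSE)
  }
  q <- stats::quantile(boot[ok], c(1 - level, level), names = FALSE)
  out <- list(
    bmc = point,
    bmcl = min(q[1], point),
    bmcu = max(q[2], point),
    bmr = bmr,
    level = level,
    model_label = "four-parameter log-logistic (parametric bootstrap)",
    B = as.integer(B),
    B_used = sum(ok),
    seed = seed,
    boot_bmc = boot,
    fit = fit
  )
  class(out) <- "bmc_boot"
  out
}

#' @export
print.bmc_boot <- function(x, digits = 4, ...) {
  cat("Benchmark concentration, BMR =", format(100 * x$bmr), "% inhibition\n")
  cat("Model:", x$model_label, "\n")
  cat(sprintf("BMC  %s uM\nBMCL %s uM  (one-sided %s%%)\nBMCU %s uM\n",
              signif(x$bmc, digits), signif(x$bmcl, digits),
              format(100 * x$level), signif(x$bmcu, digits)))
  cat("Bootstrap:", x$B_used, "of", x$B, "refits converged",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  invisible(x)
}
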