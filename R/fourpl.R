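#' Four-parameter log-logistic response function
#'
#' Evaluates the four-parameter log-logistic (4PL) model used for
#' concentration-response curves of acetylcholinesterase (AChE) inhibition,
#' \deqn{f(c) = bottom + \frac{top - bottom}{1 + (c/\mathrm{IC_{50}})^{hill}},}
#' parameterised by \code{log10_ic50} so that the midpoint is estimated on the
#' log-concentration scale. With \code{hill > 0} the curve decreases from
#' \code{top} (full remaining activity, approached as \eqn{c \to 0}) to
#' \code{bottom} (approached as \eqn{c \to \infty}); at \eqn{c =
#' \mathrm{IC_{50}}} the response is exactly \code{(top + bottom) / 2}.
#'
#' @param conc vector of concentrations (uM), strictly positive.
#' @param top,bottom upper and lower asymptotes (\% remaining activity).
#' @param log10_ic50 base-10 log of the midpoint concentration (log10 uM).
#' @param hill Hill slope (dimensionless); positive for inhibition curves.
#' @return Numeric vector of predicted \% remaining activity.
#' @seealso [fit_fourpl()]
#' @export
#' @examples
#' fourpl_response(1, top = 100, bottom = 0, log10_ic50 = 0, hill = 1) # 50
fourpl_response <- function(conc, top, bottom, log10_ic50, hill) {
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("`conc` must be finite and strictly positive", call. = FALSE)
  }
  bottom + (top - bottom) / (1 + 10^((log10(conc) - log10_ic50) * hill))
}

#' Validate replicated concentration-response data
#'
#' Checks the invariants assumed by the curve-fitting and benchmark
#' concentration machinery: strictly positive concentrations, finite responses
#' on the percent-of-control scale, and at least four distinct concentrations
#' (the model has four free parameters). Vehicle controls (concentration 0)
#' must not appear: they define the 100\% normalisation, not a point on the
#' log-concentration axis.
#'
#' @param conc vector of concentrations (uM), one entry per measurement
#'   (replicates repeat the concentration).
#' @param activity vector of \% remaining AChE activity, same length.
#' @return Invisibly, a data frame with columns \code{conc} and
#'   \code{activity}; an error is thrown on any violated invariant.
#' @export
validate_cr_data <- function(conc, activity) {
  if (length(conc) != length(activity)) {
    stop("`conc` and `activity` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentrations must be finite and strictly positive ",
         "(vehicle controls do not belong on the log-concentration axis)",
         call. = FALSE)
  }
  if (any(!is.finite(activity))) {
    stop("responses must be finite", call. = FALSE)
  }
  n_distinct <- length(unique(conc))
  if (n_distinct < 4L) {
    stop("at least 4 distinct concentrations are required to fit the ",
         "four-parameter model (got ", n_distinct, ")", call. = FALSE)
  }
  invisible(data.frame(conc = conc, activity = activity))
}

# Deterministic restart grid around a base start; first row is the base start.
fourpl_start_grid <- function(start) {
  hills <- c(start$hill, 0.5, 2, 3, 0.3)
  shifts <- c(0, 0.5, -0.5, 1, -1)
  lapply(seq_along(hills), function(i) {
    list(top = start$top, bottom = start$bottom,
         log10_ic50 = start$log10_ic50 + shifts[i], hill = hills[i])
  })
}

#' Fit a four-parameter log-logistic concentration-response curve
#'
#' Least-squares fit of the 4PL model (see [fourpl_response()]) to
#' replicate-level AChE inhibition data, the standard "log(inhibitor) vs
#' response, variable slope" analysis for in vitro potency estimation. Fitting
#' is unweighted on the individual replicate measurements (not replicate
#' means). Bounded Gauss-Newton ([stats::nls()] with the \code{"port"}
#' algorithm) is used, with a deterministic grid of restarts if the first
#' attempt fails to converge; if no attempt converges an error is thrown
#' rather than returning a fabricated estimate.
#'
#' Default bounds follow common practice for \%-of-control data:
#' \code{bottom} in \eqn{[-10, 50]}, \code{top} in \eqn{[50, 120]}. Setting
#' \code{constrain_asymptotes = TRUE} fixes \code{top = 100}, \code{bottom =
#' 0} instead of estimating them.
#'
#' @param formula two-sided formula \code{activity ~ conc} naming the response
#'   (\% remaining activity) and predictor (concentration, uM) in \code{data}.
#' @param data data frame containing the variables in \code{formula}, one row
#'   per individual measurement.
#' @param start optional named list with elements \code{top}, \code{bottom},
#'   \code{log10_ic50}, \code{hill}; by default the asymptotes start at the
#'   extreme observed responses, \code{log10_ic50} at the concentration whose
#'   mean response is nearest halfway between them, and \code{hill} at 1.
#' @param lower,upper bounds for \code{(top, bottom, log10_ic50, hill)}.
#' @param constrain_asymptotes if \code{TRUE}, fix \code{top = 100} and
#'   \code{bottom = 0} (two free parameters).
#' @param compound optional compound label carried into the fit object.
#' @param maxiter maximum iterations per attempt.
#' @return An object of class \code{"fourpl"}: a list with components
#'   \code{coefficients} (named vector \code{top}, \code{bottom},
#'   \code{log10_ic50}, \code{hill}), \code{vcov}, \code{sigma} (residual
#'   standard deviation), \code{rss}, \code{converged}, \code{trend_warning}
#'   (\code{TRUE} when the data show no decreasing trend), \code{data},
#'   \code{fitted}, \code{residuals}, \code{df.residual}, \code{n_attempts}
#'   and \code{call}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{vcov}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{plot}, \code{simulate}, [ic50()].
#' @export
#' @examples
#' d <- simulate_inhibition_curve(ic50 = 0.38, seed = 1)
#' fit <- fit_fourpl(activity_percent ~ concentration_uM, d)
#' ic50(fit)
fit_fourpl <- function(formula, data, start = NULL,
                       lower = c(top = 50, bottom = -10, log10_ic50 = -8,
                                 hill = -10),
                       upper = c(top = 120, bottom = 50, log10_ic50 = 8,
                                 hill = 10),
                       constrain_asymptotes = FALSE, compound = NULL,
                       maxiter = 200L) {
  cl <- match.call()
  # na.pass so missing responses reach the validator instead of being
  # silently dropped (which would also shrink the concentration design)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  if (ncol(mf) != 2L) {
    stop("`formula` must have the form activity ~ concentration", call. = FALSE)
  }
  activity <- mf[[1L]]
  conc <- mf[[2L]]
  validate_cr_data(conc, activity)

  # no-decreasing-trend check on per-concentration means (warn, still fit)
  mu <- tapply(activity, conc, mean)
  trend <- stats::cor(log10(as.numeric(names(mu))), as.numeric(mu),
                      method = "spearman")
  trend_warning <- !is.na(trend) && trend >= 0
  if (trend_warning) {
    warning("responses show no decreasing trend with concentration; ",
            "the fitted curve may be uninformative", call. = FALSE)
  }

  if (is.null(start)) {
    half <- (max(mu) + min(mu)) / 2
    start <- list(
      top = min(max(activity), upper[["top"]]),
      bottom = max(min(activity), lower[["bottom"]]),
      log10_ic50 = log10(as.numeric(names(mu))[which.min(abs(mu - half))]),
      hill = 1
    )
    start$top <- max(start$top, lower[["top"]])
    start$bottom <- min(start$bottom, upper[["bottom"]])
  }

  df_fit <- data.frame(conc = conc, activity = activity)
  if (constrain_asymptotes) {
    model <- activity ~ fourpl_response(conc, 100, 0, log10_ic50, hill)
    keep <- c("log10_ic50", "hill")
  } else {
    model <- activity ~ fourpl_response(conc, top, bottom, log10_ic50, hill)
    keep <- c("top", "bottom", "log10_ic50", "hill")
  }

  fit <- NULL
  n_attempts <- 0L
  for (st in fourpl_start_grid(start)) {
    n_attempts <- n_attempts + 1L
    ans <- try(stats::nls(
      model, data = df_fit, start = st[keep], algorithm = "port",
      lower = lower[keep], upper = upper[keep],
      control = stats::nls.control(maxiter = maxiter, warnOnly = FALSE)
    ), silent = TRUE)
    if (!inherits(ans, "try-error") && isTRUE(ans$convInfo$isConv)) {
      fit <- ans
      break
    }
  }
  if (is.null(fit)) {
    stop("four-parameter fit failed to converge after ", n_attempts,
         " bounded restarts", call. = FALSE)
  }

  cf <- c(top = 100, bottom = 0, log10_ic50 = NA_real_, hill = NA_real_)
  cf[names(stats::coef(fit))] <- stats::coef(fit)
  vc_free <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, length(keep), length(keep),
           dimnames = list(keep, keep))
  })
  vc <- matrix(0, 4L, 4L,
               dimnames = list(names(cf), names(cf)))
  vc[keep, keep] <- vc_free
  res <- stats::resid(fit)
  dfres <- length(res) - length(keep)

  structure(list(
    coefficients = cf,
    vcov = vc,
    sigma = sqrt(sum(res^2) / dfres),
    rss = sum(res^2),
    converged = TRUE,
    trend_warning = trend_warning,
    constrained = constrain_asymptotes,
    data = df_fit,
    fitted = stats::fitted(fit),
    residuals = as.numeric(res),
    df.residual = dfres,
    n_attempts = n_attempts,
    compound = compound,
    call = cl
  ), class = "fourpl")
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
vcov.fourpl <- function(object, ...) object$vcov

#' @export
fitted.fourpl <- function(object, ...) object$fitted

#' @export
residuals.fourpl <- function(object, ...) object$residuals

#' Predict remaining activity from a fitted curve
#'
#' @param object a \code{"fourpl"} fit.
#' @param newdata either a numeric vector of concentrations (uM) or a data
#'   frame with a \code{conc} column; defaults to the fitted design.
#' @param ... unused.
#' @return Predicted \% remaining activity.
#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$data$conc
  } else if (is.data.frame(newdata)) {
    newdata$conc
  } else {
    newdata
  }
  cf <- coef(object)
  fourpl_response(conc, cf[["top"]], cf[["bottom"]], cf[["log10_ic50"]],
                  cf[["hill"]])
}

#' Half-maximal inhibitory concentration from a fitted curve
#'
#' @param object a converged \code{"fourpl"} fit.
#' @param ... passed to methods.
#' @return IC50 in uM (\code{10^log10_ic50}).
#' @export
ic50 <- function(object, ...) UseMethod("ic50")

#' @rdname ic50
#' @export
ic50.fourpl <- function(object, ...) {
  if (!isTRUE(object$converged)) {
    stop("cannot extract an IC50 from a non-converged fit", call. = FALSE)
  }
  10^object$coefficients[["log10_ic50"]]
}

#' @export
print.fourpl <- function(x, digits = 4, ...) {
  cat("Four-parameter log-logistic concentration-response fit\n")
  if (!is.null(x$compound)) cat("Compound:", x$compound, "\n")
  print(signif(coef(x), digits))
  cat("IC50:", signif(ic50(x), digits), "uM",
      if (x$constrained) "(asymptotes fixed at 100/0)" else "", "\n")
  cat("Residual SD:", signif(x$sigma, digits), "% on",
      x$df.residual, "df\n")
  if (x$trend_warning) cat("Warning: no decreasing trend in the data\n")
  invisible(x)
}

#' @export
summary.fourpl <- function(object, level = 0.95, ...) {
  cf <- coef(object)
  se <- sqrt(diag(vcov(object)))
  tab <- cbind(Estimate = cf, `Std. Error` = se,
               `t value` = ifelse(se > 0, cf / se, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  l10 <- cf[["log10_ic50"]]
  se_l10 <- se[["log10_ic50"]]
  out <- list(coefficients = tab, sigma = object$sigma,
              df.residual = object$df.residual, rss = object$rss,
              ic50 = 10^l10,
              ic50_ci = 10^(l10 + c(-1, 1) * z * se_l10),
              level = level, compound = object$compound,
              trend_warning = object$trend_warning)
  class(out) <- "summary.fourpl"
  out
}

#' @export
print.summary.fourpl <- function(x, digits = 4, ...) {
  cat("Four-parameter log-logistic concentration-response fit\n")
  if (!is.null(x$compound)) cat("Compound:", x$compound, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("\nIC50:", signif(x$ic50, digits), "uM  (",
      format(100 * x$level), "% CI ", signif(x$ic50_ci[1], digits), "-",
      signif(x$ic50_ci[2], digits), " uM, delta method on log10 scale)\n",
      sep = "")
  cat("Residual SD:", signif(x$sigma, digits), "% on", x$df.residual, "df\n")
  invisible(x)
}

#' @export
plot.fourpl <- function(x, n_grid = 200, xlab = "Concentration (uM)",
                        ylab = "Remaining AChE activity (%)", main = NULL,
                        ...) {
  rng <- range(x$data$conc)
  grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n_grid)
  graphics::plot(x$data$conc, x$data$activity, log = "x", xlab = xlab,
                 ylab = ylab,
                 main = if (is.null(main)) x$compound else main, ...)
  graphics::lines(grid, predict(x, grid))
  cf <- coef(x)
  graphics::abline(v = ic50(x), lty = 3)
  graphics::abline(h = (cf[["top"]] + cf[["bottom"]]) / 2, lty = 3)
  invisible(x)
}

#' Simulate replicate datasets from a fitted curve
#'
#' Draws new response vectors at the fitted design points, adding i.i.d.
#' Gaussian noise with the fit's residual standard deviation (the parametric
#' bootstrap scheme used by [bmc_bootstrap()]).
#'
#' @param object a \code{"fourpl"} fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed; the RNG state is restored afterwards.
#' @param ... unused.
#' @return A data frame with one column per simulation, rows matching
#'   \code{object$data}.
#' @export
simulate.fourpl <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  mu <- object$fitted
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), 0, object$sigma), simplify = FALSE
  ), col.names = paste0("sim_", seq_len(nsim)))
  out
}

# RNG bookkeeping so seeded helpers do not perturb the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
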