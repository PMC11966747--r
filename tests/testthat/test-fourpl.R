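test_that("noiseless model-generated data are interpolated essentially exactly", {
  d <- noiseless_curve(ic50 = 1)
  fit <- fit_curve(d)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-10)
  expect_lt(abs(coef(fit)[["log10_ic50"]]), 1e-6)
  expect_lt(abs(ic50(fit) - 1), 1e-6)
  expect_lt(abs(coef(fit)[["hill"]] - 1), 1e-6)
  expect_lt(abs(coef(fit)[["top"]] - 100), 1e-5)
  expect_lt(abs(coef(fit)[["bottom"]]), 1e-5)

  # ic50 is plain exponentiation of the fitted log-midpoint
  d2 <- noiseless_curve(ic50 = 0.380)
  fit2 <- fit_curve(d2)
  expect_equal(coef(fit2)[["log10_ic50"]], log10(0.380), tolerance = 1e-6)
  expect_equal(ic50(fit2), 0.380, tolerance = 1e-6)
})

test_that("constrained fit pins the asymptotes at 100 and 0", {
  d <- noiseless_curve(ic50 = 0.5)
  fit <- fit_curve(d, constrain_asymptotes = TRUE)
  expect_identical(coef(fit)[["top"]], 100)
  expect_identical(coef(fit)[["bottom"]], 0)
  expect_equal(ic50(fit), 0.5, tolerance = 1e-6)
})

test_that("midpoint, limits and monotonicity hold across parameter grids", {
  for (ic in c(0.05, 1, 27.7)) {
    for (hill in c(0.6, 1, 2.3)) {
      d <- noiseless_curve(ic50 = ic, hill = hill)
      fit <- fit_curve(d)
      cf <- coef(fit)
      # response at the fitted IC50 is exactly the asymptote midpoint
      expect_equal(predict(fit, ic50(fit)),
                   (cf[["top"]] + cf[["bottom"]]) / 2, tolerance = 1e-12)
      # limits: top as c -> 0+, bottom as c -> Inf
      expect_equal(predict(fit, ic * 1e-12), cf[["top"]],
                   tolerance = 1e-4)
      expect_lt(abs(predict(fit, ic * 1e12) - cf[["bottom"]]), 1e-4)
      # strictly decreasing in concentration for hill > 0
      grid <- predict(fit, ic * 10^seq(-2, 2, length.out = 50))
      expect_true(all(diff(grid) < 0))
    }
  }
})

test_that("input validation refuses unusable designs", {
  d3 <- data.frame(concentration_uM = rep(c(0.1, 1, 10), each = 3),
                   activity_percent = rep(c(90, 50, 10), each = 3))
  expect_error(fit_curve(d3), "4 distinct concentrations")
  expect_error(
    fit_curve(data.frame(concentration_uM = c(0, 0.1, 1, 10),
                         activity_percent = c(100, 90, 50, 10))),
    "strictly positive")
  expect_error(
    fit_curve(data.frame(concentration_uM = c(0.01, 0.1, 1, 10),
                         activity_percent = c(100, NA, 50, 10))),
    "finite")
  expect_error(fourpl_response(-1, 100, 0, 0, 1), "positive")
})

test_that("non-decreasing responses warn but still return a fit", {
  d <- noiseless_curve(ic50 = 1)
  d$activity_percent <- 100 - d$activity_percent  # increasing curve
  expect_warning(fit <- fit_curve(d), "no decreasing trend")
  expect_true(fit$trend_warning)
  expect_s3_class(fit, "fourpl")
})

test_that("triplicate noisy curves recover the true IC50 (fixed-seed median)", {
  rel <- vapply(1:20, function(s) {
    d <- simulate_inhibition_curve(ic50 = 0.38, seed = s)
    abs(ic50(fit_curve(d)) - 0.38) / 0.38
  }, numeric(1))
  expect_lt(median(rel), 0.15)
})

test_that("fit object methods are coherent", {
  d <- simulate_inhibition_curve(ic50 = 0.38, seed = 11)
  fit <- fit_curve(d)
  expect_equal(fitted(fit) + residuals(fit), d$activity_percent,
               ignore_attr = TRUE)
  expect_equal(length(residuals(fit)), nrow(d))
  # covariance: symmetric, positive semidefinite
  vc <- vcov(fit)
  expect_identical(vc, t(vc))
  expect_true(all(eigen(vc, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  sm <- summary(fit)
  expect_true(sm$ic50_ci[1] < ic50(fit) && ic50(fit) < sm$ic50_ci[2])
  expect_output(print(fit), "IC50")
  expect_output(print(sm), "Residual SD")
  # simulate(): right shape, deterministic under a seed, noise at sigma
  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(nrow(d), 3L))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("ic50 refuses a non-converged fit", {
  d <- noiseless_curve(ic50 = 1)
  fit <- fit_curve(d)
  fit$converged <- FALSE
  expect_error(ic50(fit), "non-converged")
  expect_error(bmc(fit), "non-converged")
})
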