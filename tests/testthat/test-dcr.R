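test_that("dose normalisation is amount over body weight", {
  expect_equal(normalize_dose(70, 70), 1)
  expect_equal(normalize_dose(15000), 15000 / 70)  # ~214.3 mg/kg
  expect_equal(normalize_dose(15000, 50), 300)
  expect_error(normalize_dose(0, 70), "positive")
  expect_error(normalize_dose(70, -1), "positive")
})

test_that("blood-concentration correction divides raw model predictions", {
  expect_equal(correct_cbmax(0.051, 10), 0.0051)
  expect_equal(correct_cbmax(0.015, 1), 0.015)
  expect_equal(correct_cbmax(1015.56), 1015.56)
  expect_error(correct_cbmax(-1), "positive")
  expect_error(correct_cbmax(1, 0), "positive")
})

test_that("EAR reproduces the published scenario values", {
  # chlorpyrifos at its NOAEL; profenofos and methyl parathion poisonings
  expect_true(agrees_with_printed(ear(0.015, 0.38), "0.040"))
  expect_equal(round(ear(1015.56, 94.5), 2), 10.75)
  expect_equal(round(ear(84.26, 0.14), 2), 601.86)
  expect_equal(ear(2, 2), 1)
  expect_error(ear(0, 1), "positive")
  expect_error(ear(1, -2), "positive")
})

test_that("the comparator EAR is stored unrounded and prints as published", {
  cmp <- dcr_comparator(0.015, 0.38)
  expect_equal(cmp$ear, 0.015 / 0.38)        # 0.0394737..., not 0.039
  expect_equal(signif(cmp$ear, 2), 0.039)
  expect_equal(dcr_comparator(0.015, 0.14)$ear, 0.015 / 0.14)
  expect_error(dcr_comparator(0.38, 0.38), "below its IC50")
  expect_error(dcr_comparator(-0.1, 0.38), "positive")
})

test_that("DCR arithmetic matches the published ratios", {
  cmp <- dcr_comparator(0.015, 0.38)
  expect_equal(dcr(cmp$ear, cmp), 1)
  expect_equal(round(dcr(10.75, cmp)), 272)
  expect_equal(round(dcr(601.86, cmp)), 15247)
  expect_equal(dcr(1, 0.5), 2)  # bare numeric comparator EAR
  expect_error(dcr(-1, cmp), "positive")
})

test_that("classification uses dcr <= cutoff as safe, tie included", {
  expect_identical(as.character(classify_dcr(1.0)), "safe")
  expect_identical(as.character(classify_dcr(38)), "not_safe")
  expect_identical(as.character(classify_dcr(0.5, cutoff = 0.1)), "not_safe")
  expect_identical(as.character(classify_dcr(c(0.1, 0.10001), 0.1)),
                   c("safe", "not_safe"))
  expect_error(classify_dcr(1, cutoff = 0), "positive")
  expect_error(classify_dcr(0), "positive")
})

test_that("DCR is linear in exposure and invariant to common rescaling", {
  cmp <- dcr_comparator(0.015, 0.38)
  set.seed(1)
  for (i in 1:20) {
    cb <- runif(1, 1e-6, 100)
    ic <- runif(1, 0.01, 100)
    k <- runif(1, 2, 50)
    d1 <- dcr(ear(cb, ic), cmp)
    # linearity in the blood concentration at fixed potency
    expect_equal(dcr(ear(k * cb, ic), cmp), k * d1, tolerance = 1e-12)
    # common unit rescaling of every concentration cancels
    cmp_k <- dcr_comparator(k * 0.015, k * 0.38)
    expect_equal(dcr(ear(k * cb, k * ic), cmp_k), d1, tolerance = 1e-12)
  }
})

test_that("a comparator-matching scenario yields DCR exactly 1", {
  fx <- op_fixture()
  sc <- data.frame(compound = "chlorpyrifos", dose_mg_per_kg = 2,
                   cbmax_oxon_uM = fx$comparator$bmcl05_uM,
                   reported_outcome = "negative")
  tab <- dcr_pipeline(sc, fx$compounds, fx$comparator)
  expect_identical(tab$dcr, 1)
  expect_identical(as.character(tab$predicted_label), "safe")
})

test_that("pipeline handles doses, corrections and bad inputs", {
  fx <- op_fixture()
  # ingested amount drives the dose at the default 70 kg body weight
  sc <- data.frame(compound = c("chlorpyrifos", "fenitrothion"),
                   dose_mg_per_kg = c(NA, 1),
                   ingested_amount_mg = c(15000, NA),
                   cbmax_oxon_uM = c(0.57, 0.13),
                   cbmax_is_corrected = c(TRUE, FALSE),
                   reported_outcome = c("positive", "unknown"))
  tab <- dcr_pipeline(sc, fx$compounds, fx$comparator)
  expect_equal(tab$dose_mg_per_kg[1], 15000 / 70)
  # raw prediction for a dimethyl organothiophosphate is divided by 10
  expect_equal(tab$ear_test[2], (0.13 / 10) / 0.84)
  expect_equal(tab$dcr, tab$ear_test / fx$comparator$ear)

  # empty in, empty out
  empty <- dcr_pipeline(fx$scenarios[0, ], fx$compounds, fx$comparator)
  expect_s3_class(empty, "dcr_table")
  expect_identical(nrow(empty), 0L)

  # unknown compound names the offending row
  bad <- fx$scenarios
  bad$compound[17] <- "parathion-XX"
  expect_error(dcr_pipeline(bad, fx$compounds, fx$comparator),
               "17.*parathion-XX")
  # outcome vocabulary is closed
  bad2 <- fx$scenarios
  bad2$reported_outcome[3] <- "maybe"
  expect_error(dcr_pipeline(bad2, fx$compounds, fx$comparator), "maybe")
})

test_that("measured blood concentrations screen as safe at ambient levels", {
  fx <- op_fixture()
  # top of the reported environmental range, most potent oxon
  rec <- screen_blood(2e-4, "methyl parathion", fx$compounds,
                      fx$comparator)
  expect_equal(rec$ear_test, 2e-4 / 0.14, tolerance = 1e-9)  # 1.43e-3
  expect_equal(round(rec$dcr, 3), 0.036)
  expect_identical(as.character(rec$predicted_label), "safe")
  rec2 <- screen_blood(2e-4, "profenofos", fx$compounds, fx$comparator)
  expect_equal(rec2$dcr, (2e-4 / 94.5) / fx$comparator$ear,
               tolerance = 1e-9)                             # ~5.4e-5
  expect_lt(rec2$dcr, 1e-4)
  expect_error(screen_blood(0, "profenofos", fx$compounds, fx$comparator),
               "positive")
  expect_error(screen_blood(1, "unknownium", fx$compounds, fx$comparator),
               "absent")
})
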