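test_that("the bundled reference dataset loads with its documented shape", {
  fx <- op_fixture()
  expect_identical(nrow(fx$scenarios), 59L)
  counts <- table(fx$scenarios$compound)
  expect_identical(counts[["chlorpyrifos"]], 11L)
  expect_identical(counts[["diazinon"]], 13L)
  expect_identical(counts[["fenitrothion"]], 22L)
  expect_identical(counts[["methyl parathion"]], 9L)
  expect_identical(counts[["profenofos"]], 1L)
  expect_identical(counts[["chlorfenvinphos"]], 3L)
  expect_identical(sum(fx$scenarios$reported_outcome == "positive"), 29L)
  expect_identical(sum(fx$scenarios$reported_outcome == "negative"), 27L)
  expect_identical(sum(fx$scenarios$reported_outcome == "unknown"), 3L)
  # potency table and comparator
  expect_setequal(fx$compounds$ic50_uM, c(0.14, 0.38, 0.84, 1.82, 27.7, 94.5))
  expect_equal(fx$comparator$ear, 0.015 / 0.38)
  # dimethyl organothiophosphates (and only those) carry the /10 correction
  expect_setequal(
    fx$compounds$name[fx$compounds$correction_divisor == 10],
    c("fenitrothion", "methyl parathion"))
})

test_that("a tampered reference table fails validation", {
  fx <- op_fixture()
  expect_error(
    dcrisk:::validate_op_fixture(fx$compounds, fx$scenarios[-1, ],
                                 fx$comparator),
    "59 rows")
  flipped <- fx$scenarios
  flipped$reported_outcome[flipped$reported_outcome == "unknown"] <-
    "negative"
  expect_error(
    dcrisk:::validate_op_fixture(fx$compounds, flipped, fx$comparator),
    "outcome counts")
  expect_error(
    dcrisk:::validate_op_fixture(fx$compounds, fx$scenarios,
                                 dcr_comparator(0.015, 0.84)),
    "comparator")
})

test_that("scenario and curve CSV schemas round-trip losslessly", {
  fx <- op_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(fx$scenarios[names(fx$scenarios) != "reported_ear_test_num" &
                                names(fx$scenarios) != "reported_dcr_num"],
                   tmp, row.names = FALSE, na = "")
  back <- read_scenario_csv(tmp)
  expect_equal(back$cbmax_oxon_uM, fx$scenarios$cbmax_oxon_uM)
  expect_identical(back$reported_dcr, fx$scenarios$reported_dcr)

  d <- simulate_inhibition_curve(ic50 = 0.38, seed = 4)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, tmp2, row.names = FALSE)
  d2 <- read_curve_csv(tmp2)
  expect_equal(d2$activity_percent, d$activity_percent)
  expect_equal(d2$concentration_uM, d$concentration_uM)

  # comparator config: YAML and JSON both resolve to the same object
  tmpy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("compound: chlorpyrifos", "bmcl05_uM: 0.015",
               "ic50_uM: 0.38"), tmpy)
  tmpj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(compound = "chlorpyrifos", bmcl05_uM = 0.015,
                            ic50_uM = 0.38), tmpj, auto_unbox = TRUE)
  expect_equal(read_comparator_config(tmpy)$ear,
               read_comparator_config(tmpj)$ear)
  expect_error(read_comparator_config(withr::local_tempfile()), "not found")
})

test_that("schema violations are reported with file and column names", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), tmp, row.names = FALSE)
  expect_error(read_curve_csv(tmp), "concentration_uM")
  expect_error(read_scenario_csv(tmp), "cbmax_oxon_uM")
  expect_error(read_compound_csv(tmp), "ic50_uM")

  # a curve with too few concentrations names the offending compound
  d <- data.frame(compound = "cpdX",
                  concentration_uM = rep(c(0.1, 1, 10), 3),
                  replicate = rep(1:3, each = 3),
                  activity_percent = 50)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, tmp2, row.names = FALSE)
  expect_error(read_curve_csv(tmp2), "cpdX")
})

test_that("printed-precision helpers count digits as printed", {
  expect_identical(count_sigfigs(c("0.040", "1.0", "38", "15247",
                                   "0.000068", "1.50", "6.8e-05")),
                   c(2L, 2L, 2L, 5L, 2L, 3L, 2L))
  expect_true(agrees_with_printed(0.0394737, "0.040"))
  expect_true(agrees_with_printed(926.47, "927"))
  expect_false(agrees_with_printed(5.467e-3, "0.0050"))
  # recomputation from 2-sf inputs may round one step away
  expect_true(agrees_with_printed(2.0879, "2.2"))
  expect_false(agrees_with_printed(2.5, "2.2"))
})
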