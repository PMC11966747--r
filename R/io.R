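#' Read replicate-level concentration-response data from CSV
#'
#' Expected columns: \code{compound}, \code{concentration_uM},
#' \code{replicate}, \code{activity_percent} -- one row per individual
#' measurement, UTF-8, header row mandatory, decimal point.
#'
#' @param path path to the CSV file.
#' @return Data frame with the four columns, validated per compound with
#'   [validate_cr_data()].
#' @export
read_curve_csv <- function(path) {
  df <- read_checked_csv(path, c("compound", "concentration_uM",
                                 "replicate", "activity_percent"))
  for (cpd in unique(df$compound)) {
    sub <- df[df$compound == cpd, ]
    tryCatch(validate_cr_data(sub$concentration_uM, sub$activity_percent),
             error = function(e) {
               stop("invalid curve data for '", cpd, "' in ", path, ": ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  df
}

#' Read a compound table from CSV
#'
#' Expected columns: \code{name}, \code{op_class}, \code{active_species},
#' \code{ic50_uM}, \code{correction_divisor}. The correction divisor must be
#' 10 for dimethyl organothiophosphates and 1 otherwise (the default
#' configuration for raw kinetic-model predictions).
#'
#' @param path path to the CSV file.
#' @return Validated data frame.
#' @export
read_compound_csv <- function(path) {
  df <- read_checked_csv(path, c("name", "op_class", "active_species",
                                 "ic50_uM", "correction_divisor"))
  if (nrow(df) > 0L) stop_unless_positive(df$ic50_uM, "ic50_uM")
  bad_class <- setdiff(df$op_class,
                       c("diethyl_organothiophosphate",
                         "dimethyl_organothiophosphate", "oxon"))
  if (length(bad_class)) {
    stop("unknown op_class value(s) in ", path, ": ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  expected <- ifelse(df$op_class == "dimethyl_organothiophosphate", 10, 1)
  if (any(df$correction_divisor != expected)) {
    stop("correction_divisor must be 10 for dimethyl organothiophosphates ",
         "and 1 otherwise", call. = FALSE)
  }
  df
}

#' Read an exposure-scenario table from CSV
#'
#' Expected columns: \code{compound}, \code{dose_mg_per_kg},
#' \code{ingested_amount_mg}, \code{body_weight_kg}, \code{cbmax_oxon_uM},
#' \code{cbmax_is_corrected}, \code{reported_outcome}, \code{source_note}.
#' Optional columns \code{reported_ear_test} and \code{reported_dcr} are read
#' as text (their printed significant digits matter for reproduction
#' diagnostics) and mirrored as numeric columns with suffix \code{_num}.
#'
#' @param path path to the CSV file.
#' @return Validated data frame.
#' @export
read_scenario_csv <- function(path) {
  df <- read_checked_csv(
    path,
    c("compound", "dose_mg_per_kg", "ingested_amount_mg", "body_weight_kg",
      "cbmax_oxon_uM", "cbmax_is_corrected", "reported_outcome",
      "source_note"),
    colClasses = c(reported_ear_test = "character",
                   reported_dcr = "character")
  )
  if (nrow(df) > 0L) stop_unless_positive(df$cbmax_oxon_uM, "cbmax_oxon_uM")
  bad <- setdiff(df$reported_outcome, c("positive", "negative", "unknown"))
  if (length(bad)) {
    stop("invalid reported_outcome value(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  has_dose <- !is.na(df$dose_mg_per_kg)
  has_amount <- !is.na(df$ingested_amount_mg)
  if (any(has_dose & has_amount) || any(!has_dose & !has_amount)) {
    stop("each scenario must carry exactly one of dose_mg_per_kg or ",
         "ingested_amount_mg", call. = FALSE)
  }
  for (col in c("reported_ear_test", "reported_dcr")) {
    if (!is.null(df[[col]])) {
      df[[paste0(col, "_num")]] <- as.numeric(df[[col]])
    }
  }
  df
}

#' Read a comparator definition from YAML or JSON
#'
#' Expected keys: \code{compound}, \code{bmcl05_uM}, \code{ic50_uM}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A [dcr_comparator()] object.
#' @export
read_comparator_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("compound", "bmcl05_uM", "ic50_uM")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys)) {
    stop("comparator config ", path, " lacks key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  dcr_comparator(cfg$bmcl05_uM, cfg$ic50_uM, cfg$compound)
}

#' Write a DCR screening table to CSV
#'
#' @param x a \code{"dcr_table"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dcr_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a curve-fit report as JSON
#'
#' @param fit a \code{"fourpl"} fit.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fourpl"))
  cf <- coef(fit)
  jsonlite::write_json(list(
    compound = fit$compound,
    top = cf[["top"]], bottom = cf[["bottom"]],
    ic50_uM = ic50(fit), hill_slope = cf[["hill"]],
    se_log10_ic50 = sqrt(vcov(fit)["log10_ic50", "log10_ic50"]),
    converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a benchmark-concentration report as JSON
#'
#' @param x a \code{"bmc_boot"} result.
#' @param path output path.
#' @param compound optional compound label.
#' @return \code{path}, invisibly.
#' @export
write_bmc_json <- function(x, path, compound = NULL) {
  stopifnot(inherits(x, "bmc_boot"))
  jsonlite::write_json(list(
    compound = compound, bmr = x$bmr, bmc_uM = x$bmc, bmcl_uM = x$bmcl,
    bmcu_uM = x$bmcu, n_bootstrap = x$B, seed = x$seed
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# read.csv wrapper that reports the file and the missing columns by name;
# colClasses entries for columns absent from the file are dropped silently
read_checked_csv <- function(path, required, colClasses = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, nrows = 1))
  cc <- NA
  if (!is.null(colClasses)) {
    keep <- intersect(names(colClasses), header)
    cc <- if (length(keep)) colClasses[keep] else NA
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cc)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
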