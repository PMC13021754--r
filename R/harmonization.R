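# Tracer harmonization and control-anchored z-scoring.
#
# Published linear Centiloid calibrations for florbetapir and florbetaben
# (whole-cerebellum reference) and the tracer-specific cortical summary
# SUVR positivity thresholds.

#' Default tracer calibration table
#'
#' Linear SUVR-to-Centiloid calibrations and amyloid-positivity thresholds
#' for [18F]florbetapir (FBP) and [18F]florbetaben (FBB):
#' Centiloid = 188.22 x SUVR - 189.16 (FBP) and
#' Centiloid = 157.15 x SUVR - 151.87 (FBB), with positivity at summary
#' SUVR >= 1.11 (FBP) and >= 1.08 (FBB).
#'
#' @return A data frame with columns `tracer`, `slope`, `intercept`,
#'   `positivity_threshold`.
#' @export
tracer_calibrations <- function() {
  data.frame(
    tracer = c("FBP", "FBB"),
    slope = c(188.22, 157.15),
    intercept = c(-189.16, -151.87),
    positivity_threshold = c(1.11, 1.08),
    stringsAsFactors = FALSE
  )
}

check_calibrations <- function(calibrations) {
  need <- c("tracer", "slope", "intercept", "positivity_threshold")
  if (!all(need %in% names(calibrations))) {
    stop("calibrations need columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(calibrations$tracer)) {
    stop("exactly one calibration per tracer is required")
  }
  if (any(calibrations$slope <= 0)) stop("calibration slopes must be positive")
  calibrations
}

#' Read or write tracer calibrations as a config file
#'
#' YAML or JSON by file extension; values default to the published
#' constants from [tracer_calibrations()].
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @param calibrations Calibration table to write.
#' @return The calibration data frame (invisibly for the writer).
#' @export
read_calibrations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported calibration format: ", ext)
  )
  check_calibrations(as.data.frame(raw, stringsAsFactors = FALSE))
}

#' @rdname read_calibrations
#' @export
write_calibrations <- function(calibrations = tracer_calibrations(), path) {
  check_calibrations(calibrations)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(as.list(calibrations), path),
    json = jsonlite::write_json(calibrations, path,
      digits = NA, auto_unbox = TRUE
    ),
    stop("unsupported calibration format: ", ext)
  )
  invisible(calibrations)
}

match_tracer <- function(tracer, calibrations) {
  idx <- match(as.character(tracer), calibrations$tracer)
  if (anyNA(idx)) {
    stop(
      "unknown tracer(s): ",
      paste(unique(tracer[is.na(idx)]), collapse = ", ")
    )
  }
  idx
}

#' Convert SUVR to Centiloid (and back)
#'
#' Exact linear maps per tracer; vectorized over both arguments.
#'
#' @param tracer Tracer code(s), e.g. "FBP" or "FBB".
#' @param suvr,centiloid Numeric values to convert.
#' @param calibrations Calibration table (default published constants).
#' @return Numeric vector of converted values.
#' @export
centiloid_from_suvr <- function(tracer, suvr, calibrations = tracer_calibrations()) {
  check_calibrations(calibrations)
  if (any(!is.finite(suvr))) stop("suvr must be finite")
  idx <- match_tracer(tracer, calibrations)
  calibrations$slope[idx] * suvr + calibrations$intercept[idx]
}

#' @rdname centiloid_from_suvr
#' @export
suvr_from_centiloid <- function(tracer, centiloid, calibrations = tracer_calibrations()) {
  check_calibrations(calibrations)
  idx <- match_tracer(tracer, calibrations)
  (centiloid - calibrations$intercept[idx]) / calibrations$slope[idx]
}

#' Call amyloid positivity from the cortical summary SUVR
#'
#' Positive iff the whole-cerebellum-referenced summary SUVR reaches the
#' tracer-specific threshold; the boundary is inclusive (configurable).
#'
#' @param tracer Tracer code(s).
#' @param summary_suvr Cortical summary SUVR value(s).
#' @param calibrations Calibration table.
#' @param inclusive Treat the threshold itself as positive (default TRUE).
#' @return Logical vector.
#' @export
is_amyloid_positive <- function(tracer, summary_suvr,
                                calibrations = tracer_calibrations(),
                                inclusive = TRUE) {
  check_calibrations(calibrations)
  idx <- match_tracer(tracer, calibrations)
  thr <- calibrations$positivity_threshold[idx]
  if (inclusive) summary_suvr >= thr else summary_suvr > thr
}

roi_columns <- function(records) {
  cols <- grep("^roi_[0-9]+$", names(records), value = TRUE)
  if (length(cols) == 0L) stop("no roi_<k> columns found")
  cols[order(as.integer(sub("^roi_", "", cols)))]
}

#' Harmonize a record table to the Centiloid scale
#'
#' Converts the `roi_*` SUVR columns to Centiloid with the tracer-specific
#' linear calibration and adds `whole_brain_centiloid` (from `summary_suvr`
#' when present, otherwise the mean over ROI Centiloids). Positivity calls
#' stay on the SUVR scale (`summary_suvr` is retained).
#'
#' @param records Record table with `tracer`, `roi_*` SUVR columns and
#'   optionally `summary_suvr`.
#' @param calibrations Calibration table.
#' @return The record table with ROI values in Centiloid and a
#'   `units` attribute set to `"centiloid"`.
#' @export
harmonize_records <- function(records, calibrations = tracer_calibrations()) {
  check_calibrations(calibrations)
  cols <- roi_columns(records)
  if (identical(attr(records, "units"), "centiloid")) {
    return(records)
  }
  for (cl in cols) {
    records[[cl]] <- centiloid_from_suvr(records$tracer, records[[cl]], calibrations)
  }
  if ("summary_suvr" %in% names(records)) {
    records$whole_brain_centiloid <- centiloid_from_suvr(
      records$tracer, records$summary_suvr, calibrations
    )
  } else {
    records$whole_brain_centiloid <- rowMeans(records[, cols, drop = FALSE])
  }
  attr(records, "units") <- "centiloid"
  records
}

#' Select the normative control group
#'
#' Controls are cognitively normal, carry no APOE e4 allele, and are
#' amyloid-negative by the tracer-specific summary SUVR threshold. Records
#' with missing covariates are excluded with a warning (no imputation).
#'
#' @param records Record table with `diagnosis`, `apoe4`, `tracer`,
#'   `summary_suvr`, `age`, `sex`.
#' @param calibrations Calibration table.
#' @return The control subset of `records`.
#' @export
select_controls <- function(records, calibrations = tracer_calibrations()) {
  need <- c("diagnosis", "apoe4", "tracer", "summary_suvr", "age", "sex")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) stop("records lack columns: ", paste(miss, collapse = ", "))
  incomplete <- !stats::complete.cases(records[, need])
  if (any(incomplete)) {
    warning(sum(incomplete), " record(s) excluded for missing covariates")
    records <- records[!incomplete, , drop = FALSE]
  }
  keep <- records$diagnosis == "CN" &
    records$apoe4 == 0 &
    !is_amyloid_positive(records$tracer, records$summary_suvr, calibrations)
  records[keep, , drop = FALSE]
}

#' Fit per-region control regression models
#'
#' Ordinary least squares of each regional measure on age and sex, fitted
#' on controls only; stores the coefficients and the control residual SD
#' per region. Regions whose residual SD is (numerically) zero are flagged
#' degenerate.
#'
#' @param controls Control records (harmonized to Centiloid).
#' @param regions Region column names (default all `roi_*` columns).
#' @return An object of class `control_model` with `coefficients`
#'   (3 x K matrix: intercept, age, sex), `resid_sd`, `regions`,
#'   `degenerate`, `n_controls`.
#' @export
fit_control_model <- function(controls, regions = NULL) {
  if (is.null(regions)) regions <- roi_columns(controls)
  if (nrow(controls) < 3L) stop("at least 3 controls are required")
  if (length(unique(controls$age)) < 2L) stop("age is degenerate among controls")
  X <- cbind(1, controls$age, controls$sex)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient control design (age/sex collinear or constant)")
  }
  coefs <- matrix(NA_real_, 3, length(regions),
    dimnames = list(c("(Intercept)", "age", "sex"), regions)
  )
  rsd <- numeric(length(regions))
  for (j in seq_along(regions)) {
    fit <- stats::lm(controls[[regions[j]]] ~ age + sex, data = controls)
    if (anyNA(stats::coef(fit))) stop("rank-deficient fit for region ", regions[j])
    coefs[, j] <- stats::coef(fit)
    rsd[j] <- stats::sd(stats::residuals(fit))
  }
  degenerate <- rsd < 1e-10
  if (any(degenerate)) {
    warning(
      "degenerate (zero residual SD) region(s): ",
      paste(regions[degenerate], collapse = ", ")
    )
  }
  structure(
    list(
      coefficients = coefs,
      resid_sd = stats::setNames(rsd, regions),
      regions = regions,
      degenerate = degenerate,
      n_controls = nrow(controls)
    ),
    class = "control_model"
  )
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf(
    "Control model: %d regions fitted on %d controls (age + sex OLS)\n",
    length(x$regions), x$n_controls
  ))
  invisible(x)
}

#' Control-anchored z-scores for a cohort
#'
#' z = (measured - predicted(age, sex)) / control residual SD, per region,
#' for every record (controls and patients alike). Regions with a residual
#' SD below `min_sd` are rejected.
#'
#' @param records Record table (harmonized to the scale the control model
#'   was fitted on).
#' @param model A [fit_control_model()] result.
#' @param min_sd Smallest acceptable control residual SD.
#' @return An n x K numeric matrix of z-scores with subject ids as rownames.
#' @export
zscore_records <- function(records, model, min_sd = 1e-8) {
  if (!inherits(model, "control_model")) stop("model must be a control_model")
  bad <- model$resid_sd < min_sd
  if (any(bad)) {
    stop(
      "control residual SD below tolerance for region(s): ",
      paste(model$regions[bad], collapse = ", ")
    )
  }
  miss <- setdiff(model$regions, names(records))
  if (length(miss) > 0L) stop("records lack region(s): ", paste(miss, collapse = ", "))
  Y <- as.matrix(records[, model$regions, drop = FALSE])
  X <- cbind(1, records$age, records$sex)
  pred <- X %*% model$coefficients
  z <- sweep(Y - pred, 2, model$resid_sd, "/")
  rownames(z) <- if ("subject_id" %in% names(records)) {
    as.character(records$subject_id)
  } else {
    NULL
  }
  z
}
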