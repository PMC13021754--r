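# Centiloid conversion, positivity calls, control selection, and
# control-anchored z-scoring.

test_that("Centiloid conversion matches the printed calibrations exactly", {
  # hand-derived: 188.22 * 1.11 - 189.16 and 157.15 * 1.08 - 151.87
  expect_equal(centiloid_from_suvr("FBP", 1.11), 19.7642, tolerance = 1e-12)
  expect_equal(centiloid_from_suvr("FBB", 1.08), 17.852, tolerance = 1e-12)
  # root of the FBP linear map
  expect_equal(centiloid_from_suvr("FBP", 189.16 / 188.22), 0, tolerance = 1e-10)
  expect_error(centiloid_from_suvr("PIB", 1.2), "unknown tracer")
  expect_error(centiloid_from_suvr("FBP", NaN), "finite")
})

test_that("Centiloid conversion is affine and inverts exactly", {
  set.seed(1)
  x <- runif(20, 0.8, 2.5)
  y <- runif(20, 0.8, 2.5)
  a <- runif(20)
  lhs <- centiloid_from_suvr("FBB", a * x + (1 - a) * y)
  rhs <- a * centiloid_from_suvr("FBB", x) + (1 - a) * centiloid_from_suvr("FBB", y)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_equal(suvr_from_centiloid("FBP", centiloid_from_suvr("FBP", x)), x,
    tolerance = 1e-12
  )
})

test_that("amyloid positivity respects tracer thresholds with inclusive boundary", {
  expect_true(is_amyloid_positive("FBP", 1.20))
  expect_false(is_amyloid_positive("FBB", 1.00))
  expect_true(is_amyloid_positive("FBP", 1.11))
  expect_true(is_amyloid_positive("FBB", 1.08))
  expect_false(is_amyloid_positive("FBP", 1.11, inclusive = FALSE))
  expect_error(is_amyloid_positive("XX", 1.2), "unknown tracer")
})

make_records <- function(diagnosis, apoe4, summary_suvr, tracer = "FBP") {
  n <- length(diagnosis)
  rec <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    visit = "baseline", tracer = tracer, age = 70 + seq_len(n),
    sex = rep_len(c(0, 1), n), diagnosis = diagnosis, apoe4 = apoe4,
    summary_suvr = summary_suvr, stringsAsFactors = FALSE
  )
  rec$roi_1 <- summary_suvr
  rec
}

test_that("control selection requires CN diagnosis, no APOE e4, amyloid negativity", {
  rec <- make_records(
    diagnosis = c("CN", "CN", "MCI", "CN", "CN"),
    apoe4 = c(0, 1, 0, 0, 0),
    summary_suvr = c(1.00, 1.00, 1.00, 1.20, 1.11)
  )
  ctl <- select_controls(rec)
  expect_identical(ctl$subject_id, "S01") # boundary 1.11 is positive
  # idempotence
  expect_identical(select_controls(ctl), ctl)
})

test_that("records with missing covariates are excluded with a warning", {
  rec <- make_records(c("CN", "CN"), c(0, NA), c(1.0, 1.0))
  expect_warning(ctl <- select_controls(rec), "missing covariates")
  expect_identical(ctl$subject_id, "S01")
})

test_that("control model recovers exact linear structure and flags degeneracy", {
  set.seed(7)
  n <- 40
  rec <- data.frame(
    subject_id = sprintf("S%02d", 1:n), age = runif(n, 60, 85),
    sex = rbinom(n, 1, 0.5), stringsAsFactors = FALSE
  )
  rec$roi_1 <- 3 + 0.5 * rec$age - 2 * rec$sex
  expect_warning(cm <- fit_control_model(rec, "roi_1"), "degenerate")
  expect_equal(unname(cm$coefficients[, 1]), c(3, 0.5, -2), tolerance = 1e-9)
  expect_true(cm$degenerate[1])
  expect_error(zscore_records(rec, cm), "below tolerance")
})

test_that("control model equals the closed-form normal-equations solution", {
  rec <- data.frame(
    subject_id = c("a", "b", "c", "d"),
    age = c(60, 70, 80, 75), sex = c(0, 1, 0, 1),
    roi_1 = c(10, 14, 13, 16), stringsAsFactors = FALSE
  )
  cm <- fit_control_model(rec, "roi_1")
  X <- cbind(1, rec$age, rec$sex)
  beta <- solve(t(X) %*% X, t(X) %*% rec$roi_1)
  expect_equal(unname(cm$coefficients[, 1]), as.numeric(beta), tolerance = 1e-9)
  expect_equal(
    unname(cm$resid_sd[1]), sd(rec$roi_1 - X %*% beta),
    tolerance = 1e-12
  )
  # permutation invariance
  cm2 <- fit_control_model(rec[c(3, 1, 4, 2), ], "roi_1")
  expect_equal(cm$coefficients, cm2$coefficients, tolerance = 1e-12)
})

test_that("z-scoring maps the fit line to 0 and +2 residual SD to z = 2", {
  set.seed(11)
  n <- 30
  ctl <- data.frame(
    subject_id = sprintf("C%02d", 1:n), age = runif(n, 60, 85),
    sex = rbinom(n, 1, 0.5), stringsAsFactors = FALSE
  )
  ctl$roi_1 <- 5 + 0.3 * ctl$age + 1.5 * ctl$sex + rnorm(n, 0, 2)
  cm <- fit_control_model(ctl, "roi_1")
  pred <- cm$coefficients[1, 1] + cm$coefficients[2, 1] * 72 + cm$coefficients[3, 1]
  probe <- data.frame(
    subject_id = c("p0", "p2"), age = 72, sex = 1,
    roi_1 = c(pred, pred + 2 * cm$resid_sd[1]), stringsAsFactors = FALSE
  )
  z <- zscore_records(probe, cm)
  expect_equal(as.numeric(z), c(0, 2), tolerance = 1e-10)
})

test_that("noise-free synthetic round trip recovers trajectory values through z-scoring", {
  truth <- synthetic_truth(
    n_biomarkers = 4, n_subtypes = 2, noise_sd = 0, seed = 21
  )
  cohort <- generate_cohort(truth, n_subjects = 60, n_controls = 10, seed = 21)
  z <- zscore_records(
    harmonize_records(cohort$records),
    control_model_from_truth(truth)
  )
  sub <- cohort$subjects
  g <- truth$grid
  for (s in which(!sub$is_control)) {
    expected <- vapply(seq_along(g$biomarkers), function(b) {
      trajectory_value(
        g, truth$subtype_orderings[[sub$latent_subtype[s]]],
        b, sub$true_stage[s]
      )
    }, numeric(1))
    expect_equal(unname(z[s, ]), expected, tolerance = 1e-6)
  }
})

test_that("fitted control model calibrates control z-scores to mean 0, SD 1", {
  truth <- synthetic_truth(n_biomarkers = 5, n_subtypes = 1, noise_sd = 1, seed = 31)
  cohort <- generate_cohort(truth, n_subjects = 50, n_controls = 250, seed = 31)
  harm <- harmonize_records(cohort$records)
  ctl <- select_controls(harm)
  expect_gte(nrow(ctl), 200)
  cm <- fit_control_model(ctl)
  z <- zscore_records(harm, cm)
  zc <- z[harm$subject_id %in% ctl$subject_id, ]
  expect_true(all(abs(colMeans(zc)) < 0.1))
  expect_true(all(apply(zc, 2, sd) > 0.9 & apply(zc, 2, sd) < 1.1))
})
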