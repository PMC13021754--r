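# Ground-truth cohort generator. The generative model mirrors the fitted
# one: each progressor carries a latent subtype (event ordering) and a
# stage; the regional z-trajectory value plus Gaussian measurement noise is
# mapped to Centiloid through region baselines (age/sex effects) and a
# per-region control-scale SD, then back to tracer SUVR through the inverse
# calibration so that harmonization round-trips exactly.

#' Define the ground truth of a synthetic amyloid cohort
#'
#' @param n_biomarkers Number of regional biomarkers (default 10).
#' @param n_subtypes Number of progression subtypes.
#' @param thresholds Per-biomarker z-event thresholds (default 1, 2, 3).
#' @param z_max Trajectory plateau (default 5).
#' @param orderings Optional list of event permutations (one per subtype);
#'   random permutations are drawn when omitted.
#' @param fractions Subtype mixture fractions (default equal; must sum to 1).
#' @param noise_sd Measurement noise SD on the z-scale, per biomarker
#'   (scalar recycled; default 1 = one control SD).
#' @param age_mean,age_sd Age distribution of the cohort (years; default
#'   72 +/- 8).
#' @param age_slope Regional Centiloid change per year of age (controls).
#' @param sex_offset Regional Centiloid offset for sex = 1.
#' @param region_intercept Regional Centiloid intercept (default centres
#'   the control baseline at 0 CL at the mean age).
#' @param control_sd Control-scale SD per region in Centiloid (the unit in
#'   which z-trajectories are expressed; default 8 CL).
#' @param tracer_prob_fbp Probability a subject is scanned with FBP (the
#'   rest use FBB).
#' @param stage_dist Stage sampling law for progressors: "uniform" over
#'   0..N (default) or a numeric vector of N+1 probabilities.
#' @param followup_mean_increment Default Poisson mean of the follow-up
#'   stage increment.
#' @param seed Integer seed (all generators are pure functions of
#'   parameters and seed).
#' @return An object of class `synthetic_truth` embedding its
#'   [event_grid()].
#' @export
synthetic_truth <- function(n_biomarkers = 10, n_subtypes = 3,
                            thresholds = c(1, 2, 3), z_max = 5,
                            orderings = NULL, fractions = NULL,
                            noise_sd = 1, age_mean = 72, age_sd = 8,
                            age_slope = 0.25, sex_offset = 1.5,
                            region_intercept = NULL, control_sd = 8,
                            tracer_prob_fbp = 0.6, stage_dist = "uniform",
                            followup_mean_increment = 2, seed = 1) {
  grid <- event_grid(n_biomarkers, thresholds, z_max)
  K <- length(grid$biomarkers)
  N <- grid$n_events
  if (is.null(orderings)) {
    set.seed(seed)
    orderings <- replicate(n_subtypes, sample_ordering(grid), simplify = FALSE)
  }
  if (!is.list(orderings)) orderings <- list(orderings)
  orderings <- lapply(orderings, function(o) check_ordering(grid, o))
  if (length(orderings) != n_subtypes) {
    stop("number of orderings must equal n_subtypes")
  }
  if (is.null(fractions)) fractions <- rep(1 / n_subtypes, n_subtypes)
  if (length(fractions) != n_subtypes || any(fractions < 0) ||
    abs(sum(fractions) - 1) > 1e-12) {
    stop("fractions must be nonnegative and sum to 1")
  }
  noise_sd <- as.numeric(noise_sd)
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, K)
  if (length(noise_sd) != K || any(noise_sd < 0)) {
    stop("noise_sd must be nonnegative, length 1 or K")
  }
  control_sd <- as.numeric(control_sd)
  if (length(control_sd) == 1L) control_sd <- rep(control_sd, K)
  if (length(control_sd) != K || any(control_sd <= 0)) {
    stop("control_sd must be positive, length 1 or K")
  }
  age_slope <- rep_len(as.numeric(age_slope), K)
  sex_offset <- rep_len(as.numeric(sex_offset), K)
  if (is.null(region_intercept)) region_intercept <- -age_slope * age_mean
  region_intercept <- rep_len(as.numeric(region_intercept), K)
  if (is.character(stage_dist)) {
    stage_dist <- match.arg(stage_dist, "uniform")
  } else {
    stage_dist <- as.numeric(stage_dist)
    if (length(stage_dist) != N + 1L || any(stage_dist < 0)) {
      stop("stage_dist must give a probability for each stage 0..N")
    }
  }
  structure(
    list(
      grid = grid,
      subtype_orderings = orderings,
      subtype_fractions = fractions,
      noise_sd = noise_sd,
      age_mean = age_mean, age_sd = age_sd,
      age_slope = age_slope, sex_offset = sex_offset,
      region_intercept = region_intercept,
      control_sd = control_sd,
      tracer_prob_fbp = tracer_prob_fbp,
      stage_dist = stage_dist,
      followup_mean_increment = followup_mean_increment,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

sample_stages <- function(truth, n) {
  N <- truth$grid$n_events
  if (identical(truth$stage_dist, "uniform")) {
    sample(0:N, n, replace = TRUE)
  } else {
    sample(0:N, n, replace = TRUE, prob = truth$stage_dist)
  }
}

# Centiloid baseline (controls) per region for given covariates: n x K.
baseline_centiloid <- function(truth, age, sex) {
  outer(age, truth$age_slope) +
    outer(sex, truth$sex_offset) +
    matrix(truth$region_intercept, length(age), length(truth$region_intercept),
      byrow = TRUE
    )
}

records_from_latents <- function(truth, subject_id, visit, age, sex,
                                 diagnosis, apoe4, tracer, stage, z_latent,
                                 calibrations) {
  K <- length(truth$grid$biomarkers)
  cl <- baseline_centiloid(truth, age, sex) +
    sweep(z_latent, 2, truth$control_sd, "*")
  suvr <- matrix(
    suvr_from_centiloid(rep(tracer, K), as.numeric(cl), calibrations),
    nrow = length(age)
  )
  summary_suvr <- suvr_from_centiloid(tracer, rowMeans(cl), calibrations)
  rec <- data.frame(
    subject_id = subject_id,
    visit = visit,
    tracer = tracer,
    age = age,
    sex = sex,
    diagnosis = diagnosis,
    apoe4 = apoe4,
    summary_suvr = summary_suvr,
    adas13 = pmax(0, 8 + 0.45 * stage + stats::rnorm(length(age), 0, 3)),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(K)) rec[[sprintf("roi_%d", j)]] <- suvr[, j]
  rec
}

#' Generate a synthetic baseline cohort
#'
#' Controls are cognitively normal APOE-negative subjects at stage 0 whose
#' regional values are baseline(age, sex) plus measurement noise;
#' progressors additionally carry the z-trajectory value of their latent
#' subtype and stage on the control-referenced scale. Centiloid values are
#' mapped back to tracer SUVR through the inverse calibration, so the
#' record table is on the scale real data arrive on. Fully reproducible
#' from the seed.
#'
#' @param truth A [synthetic_truth()].
#' @param n_subjects Number of progressors (stage sampled from the truth's
#'   stage law; some may land at stage 0).
#' @param n_controls Number of designed controls.
#' @param seed Integer seed (defaults to the truth's).
#' @return A list of class `synthetic_cohort`: `records` (one row per
#'   scan, SUVR scale) and `subjects` (latent truth per subject:
#'   `true_stage`, `true_subtype` -- `NA` at stage 0 -- `latent_subtype`,
#'   and the latent z-matrix as an attribute).
#' @export
generate_cohort <- function(truth, n_subjects = 600, n_controls = 200,
                            seed = truth$seed) {
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  if (n_subjects <= 0 || n_controls <= 0) {
    stop("n_subjects and n_controls must be positive")
  }
  set.seed(seed)
  grid <- truth$grid
  K <- length(grid$biomarkers)
  N <- grid$n_events
  C <- length(truth$subtype_orderings)
  n <- n_subjects + n_controls
  calibrations <- tracer_calibrations()

  is_control <- c(rep(FALSE, n_subjects), rep(TRUE, n_controls))
  subject_id <- sprintf("S%04d", seq_len(n))
  age <- stats::rnorm(n, truth$age_mean, truth$age_sd)
  sex <- stats::rbinom(n, 1, 0.5)
  tracer <- ifelse(stats::runif(n) < truth$tracer_prob_fbp, "FBP", "FBB")

  stage <- integer(n)
  stage[!is_control] <- sample_stages(truth, n_subjects)
  latent_subtype <- sample.int(C, n, replace = TRUE, prob = truth$subtype_fractions)

  apoe4 <- integer(n)
  apoe4[!is_control] <- stats::rbinom(n_subjects, 2, 0.35)
  # Diagnosis drifts towards MCI/AD with stage (cosmetic; controls are CN).
  p_ad <- pmin(0.75, 0.02 + 0.022 * stage)
  p_mci <- pmin(0.6, 0.15 + 0.015 * stage)
  u <- stats::runif(n)
  diagnosis <- ifelse(u < p_ad, "AD", ifelse(u < p_ad + p_mci, "MCI", "CN"))
  diagnosis[is_control] <- "CN"

  traj <- lapply(truth$subtype_orderings, function(o) trajectory_matrix(grid, o))
  g <- matrix(0, n, K)
  for (s in which(!is_control)) {
    g[s, ] <- traj[[latent_subtype[s]]][, stage[s] + 1L]
  }
  z_latent <- g + matrix(stats::rnorm(n * K), n, K) %*% diag(truth$noise_sd, K)

  records <- records_from_latents(
    truth, subject_id, "baseline", age, sex, diagnosis, apoe4, tracer,
    stage, z_latent, calibrations
  )
  subjects <- data.frame(
    subject_id = subject_id,
    is_control = is_control,
    true_stage = stage,
    true_subtype = ifelse(stage == 0L, NA_integer_, latent_subtype),
    latent_subtype = latent_subtype,
    stringsAsFactors = FALSE
  )
  attr(subjects, "z_latent") <- z_latent
  structure(
    list(records = records, subjects = subjects, truth = truth, seed = seed),
    class = "synthetic_cohort"
  )
}

#' Generate follow-up scans for a synthetic cohort
#'
#' Each subject is re-sampled at stage + a Poisson increment (capped at N)
#' along the same latent subtype, with a fresh noise draw and a follow-up
#' interval in days; ages advance by the interval.
#'
#' @param cohort A [generate_cohort()] result.
#' @param truth The matching [synthetic_truth()].
#' @param mean_stage_increment Poisson mean of the stage increment
#'   (nonnegative; default from the truth).
#' @param interval_mean_days,interval_sd_days Follow-up interval law
#'   (Gaussian, truncated at 90 days; default 915 +/- 431).
#' @param seed Integer seed.
#' @return A list with `records` (visit = "followup", carrying
#'   `interval_days`) and `subjects` (true follow-up stages and increments).
#' @export
generate_followup <- function(cohort, truth = cohort$truth,
                              mean_stage_increment = truth$followup_mean_increment,
                              interval_mean_days = 915,
                              interval_sd_days = 431,
                              seed = cohort$seed + 1L) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("cohort must come from generate_cohort")
  }
  if (!is.finite(mean_stage_increment) || mean_stage_increment < 0) {
    stop("mean_stage_increment must be nonnegative")
  }
  set.seed(seed)
  grid <- truth$grid
  K <- length(grid$biomarkers)
  N <- grid$n_events
  sub <- cohort$subjects
  rec <- cohort$records
  n <- nrow(sub)
  calibrations <- tracer_calibrations()

  increment <- if (mean_stage_increment == 0) {
    rep(0L, n)
  } else {
    stats::rpois(n, mean_stage_increment)
  }
  new_stage <- pmin(N, sub$true_stage + increment)
  interval_days <- pmax(90, round(stats::rnorm(n, interval_mean_days, interval_sd_days)))
  age <- rec$age + interval_days / 365.25

  traj <- lapply(truth$subtype_orderings, function(o) trajectory_matrix(grid, o))
  g <- t(vapply(seq_len(n), function(s) {
    traj[[sub$latent_subtype[s]]][, new_stage[s] + 1L]
  }, numeric(K)))
  z_latent <- g + matrix(stats::rnorm(n * K), n, K) %*% diag(truth$noise_sd, K)

  records <- records_from_latents(
    truth, sub$subject_id, "followup", age, rec$sex, rec$diagnosis,
    rec$apoe4, rec$tracer, new_stage, z_latent, calibrations
  )
  records$interval_days <- interval_days
  # Degenerate check: no increment and no noise reproduces baseline values
  # up to the age term, which we also freeze in that case for exactness.
  if (mean_stage_increment == 0 && all(truth$noise_sd == 0)) {
    records$age <- rec$age
    base_cols <- c(roi_columns(rec), "summary_suvr", "adas13")
    records[base_cols] <- rec[base_cols]
  }
  subjects <- data.frame(
    subject_id = sub$subject_id,
    true_stage = new_stage,
    increment = increment,
    latent_subtype = sub$latent_subtype,
    stringsAsFactors = FALSE
  )
  attr(subjects, "z_latent") <- z_latent
  list(records = records, subjects = subjects, seed = seed)
}

#' Exact control model implied by a synthetic truth
#'
#' The generative analogue of [fit_control_model()]: regional intercepts,
#' age slopes and sex offsets equal the truth's baseline coefficients, and
#' the residual scale is the truth's control-scale SD (the unit in which
#' z-trajectories are generated), so that z-scoring a noise-free cohort
#' recovers the trajectory values exactly.
#'
#' @param truth A [synthetic_truth()].
#' @return A `control_model`.
#' @export
control_model_from_truth <- function(truth) {
  K <- length(truth$grid$biomarkers)
  regions <- sprintf("roi_%d", seq_len(K))
  coefs <- rbind(
    truth$region_intercept,
    truth$age_slope,
    truth$sex_offset
  )
  dimnames(coefs) <- list(c("(Intercept)", "age", "sex"), regions)
  structure(
    list(
      coefficients = coefs,
      resid_sd = stats::setNames(truth$control_sd, regions),
      regions = regions,
      degenerate = rep(FALSE, K),
      n_controls = NA_integer_
    ),
    class = "control_model"
  )
}

#' Write / read a synthetic cohort to disk
#'
#' Records go to CSV (one row per scan, SUVR scale), the latent truth to a
#' sidecar JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The output paths (invisibly); the reader returns the records and
#'   truth.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, "records.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(cohort$records, rec_path, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      biomarkers = truth$grid$biomarkers,
      thresholds = truth$grid$thresholds,
      z_max = truth$grid$z_max,
      subtype_orderings = truth$subtype_orderings,
      subtype_fractions = truth$subtype_fractions,
      noise_sd = truth$noise_sd,
      control_sd = truth$control_sd,
      seed = truth$seed,
      subjects = cohort$subjects
    ),
    truth_path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(c(records = rec_path, truth = truth_path))
}

#' @rdname write_cohort
#' @param dir Directory written by [write_cohort()].
#' @export
read_cohort <- function(dir) {
  records <- utils::read.csv(file.path(dir, "records.csv"),
    stringsAsFactors = FALSE
  )
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
    simplifyVector = TRUE
  )
  truth$subtype_orderings <- as_ordering_list(truth$subtype_orderings)
  list(records = records, truth = truth)
}
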