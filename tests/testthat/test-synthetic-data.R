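# Ground-truth cohort generator: construction guarantees, seeded
# reproducibility, follow-up increments, stage law, and voxel volumes.

test_that("noise-free generation places subjects exactly on their trajectories", {
  truth <- synthetic_truth(n_biomarkers = 3, n_subtypes = 1, noise_sd = 0, seed = 2)
  cohort <- generate_cohort(truth, n_subjects = 40, n_controls = 10, seed = 2)
  z <- attr(cohort$subjects, "z_latent")
  sub <- cohort$subjects
  # controls and stage-0 progressors sit at z = 0 exactly
  at0 <- sub$true_stage == 0
  expect_true(all(abs(z[at0, ]) < 1e-12))
  # a subject at the stage where event (i, z) occurs has z_i equal to the threshold
  g <- truth$grid
  ord <- truth$subtype_orderings[[1]]
  for (p in seq_len(g$n_events - 1L)) { # stage N plateaus at z_max instead
    hit <- which(!sub$is_control & sub$true_stage == p)
    if (length(hit) == 0) next
    ev <- ord[p]
    b <- g$events$biomarker[ev]
    expect_equal(
      unname(z[hit, b]),
      rep(g$events$level[ev], length(hit)),
      tolerance = 1e-12
    )
  }
})

test_that("generation is a pure function of parameters and seed", {
  truth <- synthetic_truth(n_biomarkers = 4, n_subtypes = 2, seed = 9)
  a <- generate_cohort(truth, 50, 20, seed = 9)
  b <- generate_cohort(truth, 50, 20, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$subjects, b$subjects)
  fa <- generate_followup(a, truth, seed = 10)
  fb <- generate_followup(b, truth, seed = 10)
  expect_identical(fa$records, fb$records)
})

test_that("orderings and fractions are validated", {
  expect_error(
    synthetic_truth(n_biomarkers = 3, n_subtypes = 1, orderings = list(1:5)),
    "permutation"
  )
  expect_error(
    synthetic_truth(n_biomarkers = 3, n_subtypes = 2, fractions = c(0.7, 0.7)),
    "sum to 1"
  )
  truth <- synthetic_truth(n_biomarkers = 3, seed = 1)
  expect_error(generate_cohort(truth, 0, 10), "positive")
})

test_that("degenerate follow-up (zero increment, zero noise) reproduces baseline", {
  truth <- synthetic_truth(n_biomarkers = 3, n_subtypes = 1, noise_sd = 0, seed = 5)
  cohort <- generate_cohort(truth, 30, 10, seed = 5)
  fu <- generate_followup(cohort, truth, mean_stage_increment = 0, seed = 6)
  cols <- c(sprintf("roi_%d", 1:3), "summary_suvr", "adas13", "age")
  expect_equal(fu$records[cols], cohort$records[cols], tolerance = 1e-12)
  expect_identical(fu$subjects$true_stage, cohort$subjects$true_stage)
})

test_that("follow-up stages cap at N and reject negative increment means", {
  truth <- synthetic_truth(n_biomarkers = 3, n_subtypes = 1, seed = 5)
  cohort <- generate_cohort(truth, 30, 5, seed = 5)
  cohort$subjects$true_stage[] <- truth$grid$n_events # push everyone to N
  fu <- generate_followup(cohort, truth, mean_stage_increment = 4, seed = 6)
  expect_true(all(fu$subjects$true_stage == truth$grid$n_events))
  expect_error(
    generate_followup(cohort, truth, mean_stage_increment = -1),
    "nonnegative"
  )
})

test_that("follow-up increments follow the Poisson law", {
  truth <- synthetic_truth(n_biomarkers = 3, n_subtypes = 1, seed = 5)
  cohort <- generate_cohort(truth, 2, 1000, seed = 5) # controls: stage 0, no cap
  fu <- generate_followup(cohort, truth, mean_stage_increment = 3, seed = 7)
  inc <- fu$subjects$increment[cohort$subjects$is_control]
  se <- sqrt(3 / length(inc)) # Poisson mean-variance oracle
  expect_lt(abs(mean(inc) - 3), 3 * se)
})

test_that("progressor stages are uniform over 0..N when so specified", {
  truth <- synthetic_truth(n_biomarkers = 5, n_subtypes = 1, seed = 13)
  cohort <- generate_cohort(truth, 2000, 1, seed = 13)
  stages <- cohort$subjects$true_stage[!cohort$subjects$is_control]
  N <- truth$grid$n_events
  tab <- tabulate(stages + 1L, nbins = N + 1L)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("cohort round-trips through CSV + JSON on disk", {
  truth <- synthetic_truth(n_biomarkers = 3, n_subtypes = 2, seed = 3)
  cohort <- generate_cohort(truth, 20, 10, seed = 3)
  dir <- tempfile("cohort_")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$records$roi_1, cohort$records$roi_1, tolerance = 1e-9)
  expect_equal(length(back$truth$subtype_orderings), 2L)
})

# ---- voxel-level volumes -------------------------------------------------

test_that("noise-free volumes reproduce Centiloid ROI means by construction", {
  spec <- volume_spec(grid_dim = c(16, 16, 8), n_components = 4, sigma = 1.6)
  cl <- matrix(runif(6 * 4, 0, 80), 6, 4)
  vols <- generate_volumes(cl, spec, noise_sd = 0)
  masks <- lapply(seq_len(4), function(i) spec$component_masks[i, ])
  means <- extract_roi_means(vols, masks)
  expect_equal(unname(means), unname(cl), tolerance = 1e-9)
  # zero weights give the zero volume
  vol0 <- generate_volumes(matrix(0, 2, 4), spec, noise_sd = 0)
  expect_true(all(vol0$data == 0))
})

test_that("volume generation rejects mismatched grids and counts", {
  spec <- volume_spec(grid_dim = c(12, 12, 6), n_components = 3, sigma = 1.5)
  expect_error(generate_volumes(matrix(0, 2, 5), spec), "must equal")
})

test_that("disjoint blobs give block-diagonal voxel covariance across subjects", {
  spec <- volume_spec(
    grid_dim = c(20, 20, 6), n_components = 2,
    centers = rbind(c(5, 5, 3), c(15, 15, 3)), sigma = 1.2
  )
  expect_false(any(spec$component_masks[1, ] & spec$component_masks[2, ]))
  set.seed(31)
  cl <- matrix(runif(200 * 2, 0, 60), 200, 2) # independent loadings
  vols <- generate_volumes(cl, spec, noise_sd = 0)
  v1 <- which(spec$component_masks[1, ])[1:5]
  v2 <- which(spec$component_masks[2, ])[1:5]
  within <- abs(cor(vols$data[, v1[1]], vols$data[, v1[2]]))
  across <- max(abs(cor(vols$data[, v1], vols$data[, v2])))
  expect_gt(within, 0.99) # same source, perfectly coherent
  expect_lt(across, 0.2) # sample-covariance oracle: independent sources
})
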