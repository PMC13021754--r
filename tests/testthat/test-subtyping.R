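# Assignment rules, positional variance diagrams, longitudinal stability,
# and change-rate summaries.

two_subtype_model <- function(K = 4, sd = 1, seed = 5) {
  g <- event_grid(K)
  set.seed(seed)
  o1 <- sample_ordering(g)
  o2 <- reverse_ordering(g, o1)
  subtype_model(g, list(o1, o2), c(0.5, 0.5), sd = sd)
}

test_that("the zero vector lands at stage 0 with no subtype", {
  m <- two_subtype_model()
  res <- assign_subjects(matrix(0, 1, 4), m, warn_ties = FALSE)
  expect_identical(res$ml_stage, 0L)
  expect_true(is.na(res$ml_subtype))
})

test_that("noise-free trajectory points are assigned to their generating cell", {
  m <- two_subtype_model()
  T2 <- trajectory_matrix(m$grid, m$orderings[[2]])
  for (k in c(5, 8)) {
    res <- assign_subjects(matrix(T2[, k + 1], 1), m, warn_ties = FALSE)
    expect_identical(res$ml_stage, as.integer(k))
    expect_identical(res$ml_subtype, 2L)
    expect_gt(res$subtype_prob, 0.5)
  }
})

test_that("identical orderings make the subtype posterior equal the fractions", {
  g <- event_grid(3)
  ord <- sample_ordering(g)
  m <- subtype_model(g, list(ord, ord), c(0.3, 0.7))
  z <- matrix(rnorm(3, 1), 1)
  post <- subject_likelihood(as.numeric(z), m)$posterior
  expect_equal(sum(post[1, ]), 0.3, tolerance = 1e-12)
  expect_equal(sum(post[2, ]), 0.7, tolerance = 1e-12)
  res <- assign_subjects(z, m, warn_ties = FALSE)
  expect_equal(res$subtype_prob, 0.7, tolerance = 1e-12)
})

test_that("duplicating a subtype with split fractions preserves the posterior", {
  m <- two_subtype_model(seed = 7)
  m3 <- subtype_model(
    m$grid, c(m$orderings, m$orderings[2]),
    c(0.5, 0.25, 0.25)
  )
  set.seed(1)
  z <- matrix(rnorm(20, 1.2, 1), 5, 4)
  a <- assign_subjects(z, m, warn_ties = FALSE)
  b <- assign_subjects(z, m3, warn_ties = FALSE)
  expect_identical(a$ml_stage, b$ml_stage)
  # merging the duplicated subtype's posterior mass reproduces the original
  for (i in 1:5) {
    pa <- rowSums(subject_likelihood(z[i, ], m)$posterior)
    pb <- rowSums(subject_likelihood(z[i, ], m3)$posterior)
    expect_equal(pa, c(pb[1], pb[2] + pb[3]), tolerance = 1e-12)
  }
})

# ---- positional variance diagrams ---------------------------------------

fake_samples <- function(grid, ords, C = 1) {
  n_kept <- length(ords)
  arr <- array(NA_integer_, c(grid$n_events, C, n_kept))
  for (j in seq_len(n_kept)) for (cc in seq_len(C)) arr[, cc, j] <- ords[[j]]
  structure(
    list(
      grid = grid, orderings = arr,
      fractions = matrix(1, n_kept, C),
      loglik = numeric(n_kept), n_iter = n_kept, burn_in = 0, thin = 1,
      n_kept = n_kept, acceptance = c(ordering = 1, fraction = NA), seed = 1
    ),
    class = "mcmc_samples"
  )
}

test_that("a single sample gives a one-hot PVD; a swapped pair splits 0.5/0.5", {
  g <- event_grid(2, c(1, 2))
  ord <- c(3, 1, 2, 4)
  pvd1 <- build_pvd(fake_samples(g, list(ord)))
  expect_true(all(pvd1$freq[[1]] %in% c(0, 1)))
  expect_equal(unname(pvd1$freq[[1]][3, 1]), 1)
  ord2 <- c(1, 3, 2, 4) # events 3 and 1 swap positions
  pvd2 <- build_pvd(fake_samples(g, list(ord, ord2)))
  expect_equal(unname(pvd2$freq[[1]][1, 1]), 0.5)
  expect_equal(unname(pvd2$freq[[1]][3, 2]), 0.5)
  expect_equal(unname(pvd2$freq[[1]][2, 3]), 1)
})

test_that("PVD rows sum to 1 and match an independent tally on a long chain", {
  g <- event_grid(2, c(1, 2, 3))
  set.seed(3)
  ords <- replicate(1000, sample.int(6), simplify = FALSE)
  pvd <- build_pvd(fake_samples(g, ords))
  expect_equal(unname(rowSums(pvd$freq[[1]])), rep(1, 6), tolerance = 1e-9)
  # independent recount
  tally <- matrix(0, 6, 6)
  for (o in ords) for (p in 1:6) tally[o[p], p] <- tally[o[p], p] + 1
  expect_equal(unname(pvd$freq[[1]]), tally / 1000, tolerance = 1e-12)
})

test_that("PVD correlation is 1 on itself, hand-checkable on 2 events, near 0 on nulls", {
  g <- event_grid(1, c(1, 2))
  a <- diag(2)
  b <- a[, 2:1]
  expect_equal(pvd_correlation(a, a)$r, 1, tolerance = 1e-12)
  # hand Pearson on the flattened 4-cell matrices: r = -1
  expect_equal(pvd_correlation(a, b)$r, -1, tolerance = 1e-12)
  expect_warning(res <- pvd_correlation(matrix(0.5, 2, 2), a), "zero-variance")
  expect_true(is.na(res$r))
  # independent near-flat PVDs decorrelate at N = 30
  gg <- event_grid(10)
  set.seed(9)
  p1 <- build_pvd(fake_samples(gg, replicate(400, sample.int(30), simplify = FALSE)))
  p2 <- build_pvd(fake_samples(gg, replicate(400, sample.int(30), simplify = FALSE)))
  expect_lt(abs(pvd_correlation(p1$freq[[1]], p2$freq[[1]])$r), 0.2)
})

# ---- longitudinal stability ----------------------------------------------

test_that("frozen pipeline reproduces identical assignments on identical scans", {
  truth <- synthetic_truth(n_biomarkers = 4, n_subtypes = 2, noise_sd = 0.5, seed = 83)
  cohort <- generate_cohort(truth, 80, 40, seed = 83)
  harm <- harmonize_records(cohort$records)
  cm <- fit_control_model(select_controls(harm))
  z <- zscore_records(harm, cm)
  model <- fit_subtypes(z, truth$grid, 2, n_restarts = 2, seed = 1)
  base <- assign_subjects(z, model,
    subject_id = cohort$records$subject_id, warn_ties = FALSE
  )
  again <- apply_longitudinal(model, cohort$records, cm)
  expect_identical(base$ml_stage, again$ml_stage)
  expect_identical(base$ml_subtype, again$ml_subtype)
  rep <- stability_metrics(base, again)
  expect_equal(rep$maintained$pct, 100)
  expect_equal(rep$stage$pct[rep$stage$category == "same"], 100)
})

test_that("a noise-free +5 stage shift advances the assigned stage by 5", {
  g <- event_grid(4)
  set.seed(11)
  ord <- sample_ordering(g)
  model <- subtype_model(g, ord)
  T <- trajectory_matrix(g, ord)
  base_stage <- c(2L, 4L, 6L) # N = 12, shifts stay on the grid
  zb <- t(T[, base_stage + 1L])
  zf <- t(T[, base_stage + 5L + 1L])
  a <- assign_subjects(zb, model, subject_id = c("a", "b", "c"), warn_ties = FALSE)
  b <- assign_subjects(zf, model, subject_id = c("a", "b", "c"), warn_ties = FALSE)
  expect_identical(b$ml_stage, a$ml_stage + 5L)
})

test_that("longitudinal assignment uses the frozen control model, not a refit", {
  truth <- synthetic_truth(n_biomarkers = 3, n_subtypes = 1, noise_sd = 0.5, seed = 87)
  cohort <- generate_cohort(truth, 60, 60, seed = 87)
  fu <- generate_followup(cohort, truth, seed = 88)
  harm_b <- harmonize_records(cohort$records)
  cm_frozen <- fit_control_model(select_controls(harm_b))
  harm_f <- harmonize_records(fu$records)
  cm_refit <- fit_control_model(select_controls(harm_f))
  z_frozen <- zscore_records(harm_f, cm_frozen)
  z_refit <- zscore_records(harm_f, cm_refit)
  expect_false(isTRUE(all.equal(z_frozen, z_refit)))
  model <- subtype_model(truth$grid, truth$subtype_orderings[[1]])
  res <- apply_longitudinal(model, fu$records, cm_frozen)
  direct <- assign_subjects(z_frozen, model,
    subject_id = fu$records$subject_id,
    visit = "followup", warn_ties = FALSE
  )
  expect_identical(res$ml_stage, direct$ml_stage)
})

test_that("follow-up subjects absent at baseline are flagged", {
  truth <- synthetic_truth(n_biomarkers = 3, n_subtypes = 1, noise_sd = 0.5, seed = 89)
  cohort <- generate_cohort(truth, 30, 30, seed = 89)
  cm <- control_model_from_truth(truth)
  model <- subtype_model(truth$grid, truth$subtype_orderings[[1]])
  expect_warning(
    res <- apply_longitudinal(model, cohort$records, cm,
      baseline_ids = cohort$records$subject_id[1:10]
    ),
    "absent at baseline"
  )
  expect_equal(length(attr(res, "unpaired")), nrow(cohort$records) - 10)
})

hand_assign <- function(ids, stages, subtypes, visit) {
  data.frame(
    subject_id = ids, visit = visit, ml_stage = as.integer(stages),
    ml_subtype = as.integer(subtypes), subtype_prob = 1,
    stringsAsFactors = FALSE
  )
}

test_that("stability metrics reproduce a hand-counted transition table", {
  base <- hand_assign(
    c("a", "b", "c", "d", "e"),
    c(0, 3, 5, 7, 2), c(NA, 1, 2, 1, 2), "baseline"
  )
  fu <- hand_assign(
    c("a", "b", "c", "d", "e"),
    c(4, 3, 0, 9, 1), c(1, 1, NA, 2, 2), "followup"
  )
  rep <- stability_metrics(base, fu)
  expect_equal(rep$n_paired, 5)
  # hand count: maintained = b (subtype1->1) and e (subtype2->2) = 2/5
  expect_equal(rep$maintained$count, 2)
  expect_equal(rep$maintained$pct, 40)
  expect_equal(rep$stage0_to_higher$count, 1) # a
  expect_equal(rep$subtype_changed$count, 1) # d
  expect_equal(unname(rep$subtype_to_stage0["subtype2"]), 1L) # c
  expect_equal(rep$stage$count[rep$stage$category == "same"], 1) # b
  expect_equal(rep$stage$count[rep$stage$category == "progressed"], 2) # a, d
  expect_equal(rep$stage$count[rep$stage$category == "regressed"], 2) # c, e
})

test_that("swapping baseline and follow-up swaps progressed and regressed", {
  set.seed(13)
  ids <- sprintf("s%02d", 1:20)
  a <- hand_assign(ids, sample(0:10, 20, TRUE), sample(1:2, 20, TRUE), "baseline")
  b <- hand_assign(ids, sample(0:10, 20, TRUE), sample(1:2, 20, TRUE), "followup")
  r1 <- stability_metrics(a, b)
  r2 <- stability_metrics(b, a)
  g1 <- setNames(r1$stage$count, r1$stage$category)
  g2 <- setNames(r2$stage$count, r2$stage$category)
  expect_equal(unname(g1["progressed"]), unname(g2["regressed"]))
  expect_equal(unname(g1["regressed"]), unname(g2["progressed"]))
  expect_equal(unname(g1["same"]), unname(g2["same"]))
})

# ---- change rates --------------------------------------------------------

test_that("annualized rates follow exact day counts and reject bad intervals", {
  base <- data.frame(
    subject_id = c("a", "b", "c"), whole_brain_centiloid = c(10, 20, 30),
    adas13 = c(5, 6, 7), stringsAsFactors = FALSE
  )
  fu <- data.frame(
    subject_id = c("a", "b", "c"),
    interval_days = c(365.25, 730.5, 0),
    whole_brain_centiloid = c(10, 30, 40), adas13 = c(5, 8, 9),
    stringsAsFactors = FALSE
  )
  expect_warning(rates <- summarize_rates(base, fu), "rejected")
  expect_equal(nrow(rates), 2)
  expect_equal(rates$rate_whole_brain_centiloid, c(0, 5)) # +10 CL over 2 y = 5/y
  expect_equal(rates$rate_adas13, c(0, 1))
})

test_that("stage-linked amyloid accrual orders subtype mean rates as generated", {
  # two subtypes with different follow-up accrual through different stage jumps
  truth <- synthetic_truth(n_biomarkers = 4, n_subtypes = 1, noise_sd = 0.2, seed = 91)
  cohort <- generate_cohort(truth, 200, 2, seed = 91)
  fast <- generate_followup(cohort, truth, mean_stage_increment = 6, seed = 92)
  slow <- generate_followup(cohort, truth, mean_stage_increment = 1, seed = 93)
  harm_b <- harmonize_records(cohort$records)
  r_fast <- summarize_rates(harm_b, harmonize_records(fast$records),
    measures = "whole_brain_centiloid"
  )
  r_slow <- summarize_rates(harm_b, harmonize_records(slow$records),
    measures = "whole_brain_centiloid"
  )
  expect_gt(
    mean(r_fast$rate_whole_brain_centiloid),
    mean(r_slow$rate_whole_brain_centiloid)
  )
})
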