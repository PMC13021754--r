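# Independent oracles, coded from the model definition without touching the
# package's C++ path: piecewise-linear trajectories via approxfun, and
# likelihoods as direct products of Normal densities.

oracle_trajectory <- function(grid, ordering, biomarker, stage) {
  N <- grid$n_events
  pos <- match(seq_len(N), ordering)
  idx <- which(grid$events$biomarker == biomarker)
  p <- pos[idx]
  z <- grid$events$level[idx]
  o <- order(p)
  xs <- c(0, p[o])
  ys <- c(0, z[o])
  if (max(p) < N) {
    xs <- c(xs, N)
    ys <- c(ys, grid$z_max)
  }
  f <- approxfun(xs, ys, rule = 2)
  out <- f(stage)
  out[stage == N] <- grid$z_max
  out
}

oracle_stage_lik <- function(z, grid, ordering, stage, sd = 1) {
  mu <- vapply(
    seq_along(grid$biomarkers),
    function(b) oracle_trajectory(grid, ordering, b, stage),
    numeric(1)
  )
  prod(dnorm(z, mu, sd))
}

# Exhaustive subtype x stage enumeration of the marginal likelihood.
oracle_subject_lik <- function(z, grid, orderings, fractions, sd = 1) {
  N <- grid$n_events
  total <- 0
  for (cc in seq_along(orderings)) {
    for (k in 0:N) {
      total <- total + fractions[cc] / (N + 1) *
        oracle_stage_lik(z, grid, orderings[[cc]], k, sd)
    }
  }
  total
}

# Small deterministic cohort on the z-scale for fitting tests.
make_z_cohort <- function(truth, n_subjects, n_controls = 0, seed = 1) {
  cohort <- generate_cohort(truth, n_subjects, max(n_controls, 1), seed = seed)
  z <- zscore_records(
    harmonize_records(cohort$records),
    control_model_from_truth(truth)
  )
  list(z = z, cohort = cohort)
}
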