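logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(M) {
  m <- apply(M, 1, max)
  m + log(rowSums(exp(M - m)))
}

expand_sd <- function(sd, K) {
  sd <- as.numeric(sd)
  if (length(sd) == 1L) sd <- rep(sd, K)
  if (length(sd) != K) stop("sd must have length 1 or K")
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("sd must be positive")
  sd
}

#' Construct a subtype progression model
#'
#' A mixture of C event orderings over a shared event grid, with mixture
#' fractions on the simplex and a per-biomarker Gaussian likelihood SD on
#' the z-scale (default 1, matching control-SD-scaled data).
#'
#' @param grid An [event_grid()].
#' @param orderings A list of integer event permutations (one per subtype),
#'   or a single permutation.
#' @param fractions Mixture fractions summing to 1 (default equal).
#' @param sd Likelihood SD per biomarker (scalar recycled).
#' @return An object of class `subtype_model`.
#' @export
subtype_model <- function(grid, orderings, fractions = NULL, sd = 1) {
  if (!inherits(grid, "event_grid")) stop("grid must be an event_grid")
  if (!is.list(orderings)) orderings <- list(orderings)
  orderings <- lapply(orderings, function(o) check_ordering(grid, o))
  C <- length(orderings)
  if (is.null(fractions)) fractions <- rep(1 / C, C)
  fractions <- as.numeric(fractions)
  if (length(fractions) != C) stop("one fraction per subtype is required")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-12) {
    stop("fractions must be nonnegative and sum to 1")
  }
  structure(
    list(
      grid = grid,
      orderings = orderings,
      fractions = fractions,
      sd = expand_sd(sd, length(grid$biomarkers)),
      n_subtypes = C
    ),
    class = "subtype_model"
  )
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf(
    "Subtype model: %d subtype(s) over %d events; fractions = %s\n",
    x$n_subtypes, x$grid$n_events,
    paste(sprintf("%.3f", x$fractions), collapse = ", ")
  ))
  if (!is.null(x$loglik)) cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' Gaussian likelihood of a z-vector at a fixed stage of one ordering
#'
#' The product over biomarkers of Normal densities centred on the
#' trajectory's expected z-value at that stage.
#'
#' @param z Numeric vector of K z-scores.
#' @param grid An [event_grid()].
#' @param ordering Event permutation.
#' @param stage Integer stage(s) in 0..N.
#' @param sd Likelihood SD (scalar or length K).
#' @param log Return the log-likelihood instead.
#' @return Numeric vector of (log-)likelihood values, one per stage.
#' @export
stage_likelihood <- function(z, grid, ordering, stage, sd = 1, log = FALSE) {
  K <- length(grid$biomarkers)
  if (length(z) != K) stop("z must have one value per biomarker")
  sd <- expand_sd(sd, K)
  stage <- as.integer(stage)
  if (any(stage < 0 | stage > grid$n_events)) stop("stage out of range")
  T <- trajectory_matrix(grid, ordering)
  ll <- vapply(stage, function(k) {
    sum(stats::dnorm(z, mean = T[, k + 1L], sd = sd, log = TRUE))
  }, numeric(1))
  if (log) ll else exp(ll)
}

#' Per-stage log-likelihood matrix for a cohort
#'
#' @param z_matrix Numeric n x K matrix of z-scores.
#' @param grid An [event_grid()].
#' @param ordering Event permutation.
#' @param sd Likelihood SD (scalar or length K).
#' @return An n x (N+1) matrix of log-likelihoods; columns are stages 0..N.
#' @export
stage_loglik_matrix <- function(z_matrix, grid, ordering, sd = 1) {
  z_matrix <- as.matrix(z_matrix)
  K <- length(grid$biomarkers)
  if (ncol(z_matrix) != K) stop("z_matrix must have K columns")
  ordering <- check_ordering(grid, ordering)
  sd <- expand_sd(sd, K)
  T <- traj_matrix_cpp(
    grid$events$biomarker, grid$events$level, ordering, K, grid$z_max
  )
  L <- stage_loglik_cpp(z_matrix, T, sd)
  colnames(L) <- as.character(0:grid$n_events)
  L
}

# Stage-marginal log-likelihood per subject under each subtype:
# log( (1/(N+1)) sum_k exp(L_sk) ), returned as an n x C matrix.
subtype_marginal_matrix <- function(z_matrix, model) {
  z_matrix <- as.matrix(z_matrix)
  grid <- model$grid
  K <- length(grid$biomarkers)
  vapply(model$orderings, function(o) {
    stage_marginal_loglik_cpp(
      z_matrix, grid$events$biomarker, grid$events$level,
      as.integer(o), model$sd, grid$z_max
    )
  }, numeric(nrow(z_matrix)))
}

#' Marginal likelihood and subtype-by-stage posterior for one subject
#'
#' The marginal mixes uniformly over stages 0..N and over subtypes with the
#' model fractions; the posterior is the normalized subtype-by-stage grid.
#'
#' @param z Numeric vector of K z-scores.
#' @param model A [subtype_model()].
#' @return A list with `marginal` (likelihood), `log_marginal`, and
#'   `posterior`, a C x (N+1) matrix summing to 1.
#' @export
subject_likelihood <- function(z, model) {
  z <- matrix(as.numeric(z), nrow = 1)
  grid <- model$grid
  C <- model$n_subtypes
  N <- grid$n_events
  logpost <- matrix(NA_real_, C, N + 1L,
    dimnames = list(NULL, as.character(0:N))
  )
  for (cc in seq_len(C)) {
    L <- stage_loglik_matrix(z, grid, model$orderings[[cc]], model$sd)
    logpost[cc, ] <- log(model$fractions[cc]) - log(N + 1) + L[1, ]
  }
  lm <- logsumexp(as.numeric(logpost))
  list(
    marginal = exp(lm),
    log_marginal = lm,
    posterior = exp(logpost - lm)
  )
}

#' Cohort log marginal likelihood under a subtype model
#'
#' @param z_matrix Numeric n x K matrix of z-scores.
#' @param model A [subtype_model()].
#' @param total Sum over subjects (default) or return the per-subject vector.
#' @return Total (or per-subject) log marginal likelihood.
#' @export
cohort_loglik <- function(z_matrix, model, total = TRUE) {
  M <- subtype_marginal_matrix(z_matrix, model)
  A <- sweep(M, 2, log(model$fractions), "+")
  ll <- row_logsumexp(A)
  if (total) sum(ll) else ll
}
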