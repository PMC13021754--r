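# Maximum-likelihood fitting of event orderings and subtype mixtures.
# Orderings are searched by greedy single-event relocation from multiple
# random starts; mixtures are fitted by EM with weighted ordering updates,
# seeded hierarchically by splitting the worst-fitting cluster.

# Data-driven warm start: events ranked by the (weighted) fraction of
# subjects whose z already exceeds the event threshold -- events crossed by
# more of the cohort come earlier. Greedy relocation then polishes it.
crossing_init <- function(z_matrix, grid, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(z_matrix))
  w <- weights / sum(weights)
  frac <- vapply(seq_len(grid$n_events), function(e) {
    bm <- grid$events$biomarker[e]
    sum(w * (z_matrix[, bm] > grid$events$level[e]))
  }, numeric(1))
  order(-frac, seq_len(grid$n_events))
}

greedy_ordering <- function(z_matrix, grid, init, sd, weights = NULL,
                            max_sweeps = 100) {
  z_matrix <- as.matrix(z_matrix)
  if (is.null(weights)) weights <- rep(1, nrow(z_matrix))
  weights <- as.numeric(weights)
  # subjects with (numerically) zero weight cannot move the objective;
  # dropping them makes mixture M-steps scale with the cluster size
  keep <- weights > 1e-8 * max(weights)
  if (!all(keep)) {
    z_matrix <- z_matrix[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  greedy_fit_cpp(
    z_matrix, grid$events$biomarker, grid$events$level,
    as.integer(init), expand_sd(sd, ncol(z_matrix)), grid$z_max,
    weights, max_sweeps
  )
}

#' Fit the maximum-likelihood event ordering for a single subtype
#'
#' Runs greedy single-event relocation from `n_restarts` random initial
#' permutations and returns the best ordering. Deterministic for a fixed
#' seed.
#'
#' @param z_matrix Numeric n x K matrix of z-scores.
#' @param grid An [event_grid()].
#' @param sd Likelihood SD on the z-scale (scalar or length K; default 1).
#' @param n_restarts Number of random initializations (default 25).
#' @param seed Optional integer seed.
#' @param weights Optional nonnegative per-subject weights (used by the
#'   mixture EM; default all 1).
#' @return A list with `ordering`, `loglik`, and `restart_logliks`.
#' @export
fit_single_subtype <- function(z_matrix, grid, sd = 1, n_restarts = 25,
                               seed = NULL, weights = NULL) {
  z_matrix <- as.matrix(z_matrix)
  if (nrow(z_matrix) < 2L) stop("at least two subjects are required")
  if (!is.null(seed)) set.seed(seed)
  N <- grid$n_events
  best <- NULL
  lls <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) {
      crossing_init(z_matrix, grid, weights)
    } else {
      sample.int(N)
    }
    res <- greedy_ordering(z_matrix, grid, init, sd, weights)
    lls[r] <- res$loglik
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best) || !is.finite(best$loglik)) {
    stop("all restarts degenerate: no finite log-likelihood found")
  }
  list(
    ordering = as.integer(best$ordering),
    loglik = best$loglik,
    restart_logliks = lls
  )
}

# EM for a fixed number of subtypes starting from given orderings/fractions.
# The observed-data log-likelihood is asserted non-decreasing at every
# iteration; the ordering M-step warm-starts greedy search from the current
# ordering with responsibility weights, which cannot decrease the objective.
em_subtypes <- function(z_matrix, grid, orderings, fractions, sd,
                        tol = 1e-4, max_iter = 100) {
  n <- nrow(z_matrix)
  C <- length(orderings)
  prev <- -Inf
  trace <- numeric(0)
  reseeded <- FALSE
  model <- subtype_model(grid, orderings, fractions, sd)
  for (it in seq_len(max_iter)) {
    M <- subtype_marginal_matrix(z_matrix, model)
    A <- sweep(M, 2, log(model$fractions), "+")
    lse <- row_logsumexp(A)
    ll <- sum(lse)
    if (ll < prev - 1e-6) {
      stop("internal error: EM log-likelihood decreased (", prev, " -> ", ll, ")")
    }
    trace <- c(trace, ll)
    if (it > 1L && (ll - prev) < tol) break
    prev <- ll

    R <- exp(A - lse)
    fr <- colMeans(R)
    empty <- which(fr < 1 / (10 * n))
    if (length(empty) > 0L) {
      if (reseeded) stop("subtype emptied during EM after reseeding")
      reseeded <- TRUE
      worst <- order(lse)[seq_len(max(2L, ceiling(n / 10)))]
      for (cc in empty) {
        res <- greedy_ordering(
          z_matrix[worst, , drop = FALSE], grid,
          model$orderings[[cc]], sd
        )
        model$orderings[[cc]] <- as.integer(res$ordering)
        fr[cc] <- length(worst) / n
      }
      fr <- fr / sum(fr)
      model$fractions <- fr
      next
    }
    new_ord <- model$orderings
    for (cc in seq_len(C)) {
      # a partial (capped-sweep) improvement step keeps EM monotone without
      # paying for full greedy convergence at every iteration
      res <- greedy_ordering(z_matrix, grid, model$orderings[[cc]], sd,
        weights = R[, cc], max_sweeps = 3
      )
      new_ord[[cc]] <- as.integer(res$ordering)
    }
    model <- subtype_model(grid, new_ord, fr / sum(fr), sd)
  }
  model$loglik <- trace[length(trace)]
  model$loglik_trace <- trace
  model
}

# Pattern-based 2-means seed for splitting a cluster: cluster the unit
# directions of subjects' residuals from the parent trajectory at their MAP
# stage, which carries progression-pattern information but not stage.
split_kmeans <- function(z_matrix, model, cluster, members) {
  T <- trajectory_matrix(model$grid, model$orderings[[cluster]])
  L <- stage_loglik_matrix(
    z_matrix[members, , drop = FALSE], model$grid,
    model$orderings[[cluster]], model$sd
  )
  stg <- max.col(L, ties.method = "first")
  resid <- z_matrix[members, , drop = FALSE] - t(T[, stg, drop = FALSE])
  nrm <- sqrt(rowSums(resid^2))
  nrm[nrm < 1e-8] <- 1
  km <- stats::kmeans(resid / nrm, centers = 2, nstart = 5)
  split(members, km$cluster)
}

# Choose the cluster to split: the MAP-assigned cluster with the largest
# mean squared residual around its trajectory at the MAP stage.
split_target <- function(z_matrix, model) {
  C <- model$n_subtypes
  post <- assign_subjects(z_matrix, model, warn_ties = FALSE)
  cl <- post$ml_subtype
  cl[is.na(cl)] <- post$ml_subtype_unrestricted[is.na(cl)]
  resvar <- rep(-Inf, C)
  for (cc in seq_len(C)) {
    idx <- which(cl == cc)
    if (length(idx) == 0L) next
    T <- trajectory_matrix(model$grid, model$orderings[[cc]])
    mu <- t(T[, post$ml_stage[idx] + 1L, drop = FALSE])
    resvar[cc] <- mean((z_matrix[idx, , drop = FALSE] - mu)^2)
  }
  list(cluster = which.max(resvar), members = which(cl == which.max(resvar)))
}

#' Fit a subtype-and-stage mixture model
#'
#' Fits mixtures of event orderings hierarchically: the single-subtype
#' solution is found by multi-start greedy search; each further subtype is
#' seeded by splitting the worst-fitting cluster of the previous solution
#' (a pattern-based 2-means seed plus `n_splits` random bipartitions of its
#' assigned subjects, keeping the best), then
#' refined by EM over responsibilities, fractions, and per-subtype
#' orderings. The log-likelihood is non-decreasing across EM iterations.
#'
#' @inheritParams fit_single_subtype
#' @param n_subtypes Number of subtypes C (>= 1).
#' @param n_splits Random bipartitions tried when seeding each split (in
#'   addition to the 2-means seed).
#' @param tol EM convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations per split.
#' @return A [subtype_model()] with `loglik` and `loglik_trace` fields.
#' @export
fit_subtypes <- function(z_matrix, grid, n_subtypes, sd = 1, n_restarts = 25,
                         n_splits = 2, seed = NULL, tol = 1e-3,
                         max_iter = 30) {
  path <- fit_subtypes_path(
    z_matrix, grid, n_subtypes,
    sd = sd, n_restarts = n_restarts,
    n_splits = n_splits, seed = seed, tol = tol, max_iter = max_iter
  )
  path[[n_subtypes]]
}

# Fit models for C = 1..max_C hierarchically, returning the whole path.
fit_subtypes_path <- function(z_matrix, grid, max_C, sd = 1, n_restarts = 25,
                              n_splits = 2, seed = NULL, tol = 1e-3,
                              max_iter = 30) {
  z_matrix <- as.matrix(z_matrix)
  if (max_C < 1L) stop("n_subtypes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(z_matrix)

  single <- fit_single_subtype(z_matrix, grid,
    sd = sd,
    n_restarts = n_restarts
  )
  m1 <- subtype_model(grid, list(single$ordering), 1, sd)
  m1$loglik <- single$loglik
  m1$loglik_trace <- single$loglik
  path <- list(m1)

  if (max_C == 1L) return(path)
  for (C in 2:max_C) {
    prev <- path[[C - 1L]]
    tgt <- split_target(z_matrix, prev)
    members <- tgt$members
    if (length(members) < 4L) members <- seq_len(n)
    best <- NULL
    for (s in seq_len(n_splits + 1L)) {
      if (s == 1L) {
        parts <- split_kmeans(z_matrix, prev, tgt$cluster, members)
        half <- parts[[1]]
        other <- parts[[2]]
        if (length(half) < 2L || length(other) < 2L) next
      } else {
        half <- sample(members, size = floor(length(members) / 2))
        other <- setdiff(members, half)
      }
      orderings <- prev$orderings
      res_a <- fit_single_subtype(z_matrix[half, , drop = FALSE], grid,
        sd = sd, n_restarts = 2
      )
      res_b <- fit_single_subtype(z_matrix[other, , drop = FALSE], grid,
        sd = sd, n_restarts = 2
      )
      orderings[[tgt$cluster]] <- res_a$ordering
      orderings[[C]] <- res_b$ordering
      fr <- prev$fractions
      fr[tgt$cluster] <- fr[tgt$cluster] * length(half) / length(members)
      fr <- c(fr, prev$fractions[tgt$cluster] * length(other) / length(members))
      fr <- pmax(fr, 1e-3)
      fr <- fr / sum(fr)
      m <- em_subtypes(z_matrix, grid, orderings, fr, sd,
        tol = tol, max_iter = max_iter
      )
      if (is.null(best) || m$loglik > best$loglik) best <- m
    }
    path[[C]] <- best
  }
  path
}

#' Kendall rank correlation between two event orderings
#'
#' Computed on the stage positions of each event under the two orderings;
#' 1 means identical orderings, -1 fully reversed.
#'
#' @param a,b Integer event permutations of equal length.
#' @return Kendall's tau.
#' @export
ordering_kendall <- function(a, b) {
  pos_a <- match(seq_along(a), a)
  pos_b <- match(seq_along(b), b)
  stats::cor(pos_a, pos_b, method = "kendall")
}

#' Match fitted subtypes to ground-truth orderings
#'
#' Enumerates assignments of fitted subtypes to true orderings and returns
#' the one maximizing the summed Kendall tau.
#'
#' @param model A fitted [subtype_model()].
#' @param true_orderings List of ground-truth event permutations.
#' @return Integer vector `perm` such that fitted subtype `c` corresponds to
#'   true subtype `perm[c]`, with the achieved `tau` matrix as an attribute.
#' @export
match_subtypes <- function(model, true_orderings) {
  C <- model$n_subtypes
  Ct <- length(true_orderings)
  tau <- matrix(NA_real_, C, Ct)
  for (i in seq_len(C)) {
    for (j in seq_len(Ct)) {
      tau[i, j] <- ordering_kendall(model$orderings[[i]], true_orderings[[j]])
    }
  }
  perms <- all_permutations(seq_len(Ct))
  best <- NULL
  best_val <- -Inf
  for (p in perms) {
    val <- sum(tau[cbind(seq_len(min(C, Ct)), p[seq_len(min(C, Ct))])])
    if (val > best_val) {
      best_val <- val
      best <- p
    }
  }
  structure(best[seq_len(C)], tau = tau)
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
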