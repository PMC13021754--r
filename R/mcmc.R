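#' MCMC sampling of ordering and fraction uncertainty
#'
#' Metropolis-Hastings over the subtype orderings and mixture fractions of a
#' fitted model. Ordering proposals swap the events at two random stage
#' positions within one random subtype; fraction proposals (for C > 1)
#' transfer a uniform perturbation between two random subtypes and are
#' rejected outright if any fraction would leave the simplex, keeping the
#' proposal symmetric. Acceptance is by likelihood ratio under uniform
#' priors. The chain is reproducible from the seed.
#'
#' @param z_matrix Numeric n x K matrix of z-scores.
#' @param model A fitted [subtype_model()] (the chain starts here).
#' @param n_iter Total iterations (default 1e5).
#' @param burn_in Iterations discarded from the stored samples (default 10%
#'   of `n_iter`); must be smaller than `n_iter`.
#' @param thin Keep every `thin`-th post-burn-in sample (default 1).
#' @param frac_step Half-width of the fraction transfer proposal.
#' @param seed Optional integer seed.
#' @return An object of class `mcmc_samples`: `orderings` (N x C x kept
#'   array), `fractions` (kept x C), `loglik` (full trace), acceptance
#'   rates, and burn-in/thinning metadata.
#' @export
mcmc_sample <- function(z_matrix, model, n_iter = 1e5, burn_in = NULL,
                        thin = 1, frac_step = 0.05, seed = NULL) {
  z_matrix <- as.matrix(z_matrix)
  if (is.null(burn_in)) burn_in <- floor(n_iter / 10)
  if (n_iter <= burn_in) stop("n_iter must exceed the burn-in length")
  if (!is.null(seed)) set.seed(seed)

  grid <- model$grid
  N <- grid$n_events
  C <- model$n_subtypes
  orderings <- model$orderings
  fractions <- model$fractions

  marg_col <- function(o) {
    stage_marginal_loglik_cpp(
      z_matrix, grid$events$biomarker, grid$events$level,
      as.integer(o), model$sd, grid$z_max
    )
  }
  M <- vapply(orderings, marg_col, numeric(nrow(z_matrix)))
  ll_of <- function(M, fr) sum(row_logsumexp(sweep(M, 2, log(fr), "+")))
  ll <- ll_of(M, fractions)

  kept_idx <- seq(burn_in + 1L, n_iter, by = thin)
  n_kept <- length(kept_idx)
  ord_store <- array(NA_integer_, dim = c(N, C, n_kept))
  frac_store <- matrix(NA_real_, n_kept, C)
  ll_trace <- numeric(n_iter)
  acc_ord <- c(0L, 0L)
  acc_frac <- c(0L, 0L)
  store_at <- integer(n_iter)
  store_at[kept_idx] <- seq_len(n_kept)

  for (it in seq_len(n_iter)) {
    move_frac <- C > 1L && stats::runif(1) < 0.5
    if (!move_frac) {
      cc <- if (C == 1L) 1L else sample.int(C, 1)
      pos <- sample.int(N, 2, replace = TRUE)
      cand <- orderings[[cc]]
      tmp <- cand[pos[1]]
      cand[pos[1]] <- cand[pos[2]]
      cand[pos[2]] <- tmp
      Mcand <- M
      Mcand[, cc] <- marg_col(cand)
      ll_new <- ll_of(Mcand, fractions)
      acc_ord[2] <- acc_ord[2] + 1L
      if (log(stats::runif(1)) < (ll_new - ll)) {
        orderings[[cc]] <- cand
        M <- Mcand
        ll <- ll_new
        acc_ord[1] <- acc_ord[1] + 1L
      }
    } else {
      ij <- sample.int(C, 2)
      delta <- stats::runif(1, -frac_step, frac_step)
      fr_new <- fractions
      fr_new[ij[1]] <- fr_new[ij[1]] + delta
      fr_new[ij[2]] <- fr_new[ij[2]] - delta
      acc_frac[2] <- acc_frac[2] + 1L
      if (all(fr_new > 0)) {
        ll_new <- ll_of(M, fr_new)
        if (log(stats::runif(1)) < (ll_new - ll)) {
          fractions <- fr_new
          ll <- ll_new
          acc_frac[1] <- acc_frac[1] + 1L
        }
      }
    }
    ll_trace[it] <- ll
    if (store_at[it] > 0L) {
      j <- store_at[it]
      for (cc in seq_len(C)) ord_store[, cc, j] <- orderings[[cc]]
      frac_store[j, ] <- fractions
    }
  }

  structure(
    list(
      grid = grid,
      orderings = ord_store,
      fractions = frac_store,
      loglik = ll_trace,
      n_iter = n_iter,
      burn_in = burn_in,
      thin = thin,
      n_kept = n_kept,
      acceptance = c(
        ordering = if (acc_ord[2] > 0) acc_ord[1] / acc_ord[2] else NA_real_,
        fraction = if (acc_frac[2] > 0) acc_frac[1] / acc_frac[2] else NA_real_
      ),
      seed = seed
    ),
    class = "mcmc_samples"
  )
}

#' @export
print.mcmc_samples <- function(x, ...) {
  cat(sprintf(
    "MCMC samples: %d iterations (%d burn-in, thin %d, %d kept); acceptance ordering %.2f\n",
    x$n_iter, x$burn_in, x$thin, x$n_kept, x$acceptance[["ordering"]]
  ))
  invisible(x)
}

#' Modal (most frequent) ordering across MCMC samples
#'
#' @param samples An [mcmc_sample()] result.
#' @param subtype Subtype index.
#' @return The most frequently visited ordering as an integer vector.
#' @export
mcmc_modal_ordering <- function(samples, subtype = 1) {
  keys <- apply(samples$orderings[, subtype, , drop = FALSE], 3, paste, collapse = ",")
  best <- names(which.max(table(keys)))
  as.integer(strsplit(best, ",", fixed = TRUE)[[1]])
}
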