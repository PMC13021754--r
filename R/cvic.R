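#' Cross-validated selection of the number of subtypes
#'
#' Subjects are partitioned into seeded folds; for each candidate number of
#' subtypes C the model is fitted on the held-in folds and the out-of-fold
#' log marginal likelihood is accumulated. The cross-validation information
#' criterion is CVIC(C) = -2 x total out-of-fold log-likelihood and the
#' selected C minimizes it. When the improvement over the next-smaller
#' model falls below `parsimony_margin`, a note flags that a more
#' parsimonious model is defensible (the final call is the analyst's).
#'
#' @param z_matrix Numeric n x K matrix of z-scores.
#' @param grid An [event_grid()].
#' @param max_C Largest number of subtypes considered.
#' @param n_folds Number of cross-validation folds (default 10).
#' @param sd Likelihood SD on the z-scale.
#' @param n_restarts,n_splits Search effort passed to [fit_subtypes()].
#' @param parsimony_margin CVIC improvement below which the note fires.
#' @param seed Optional integer seed (folds and fits).
#' @return A list with `cvic` (named per C), `chosen`, `oof_loglik`,
#'   `per_fold` (folds x C matrix), `folds`, and `note`.
#' @export
cvic_select <- function(z_matrix, grid, max_C = 3, n_folds = 10, sd = 1,
                        n_restarts = 5, n_splits = 2,
                        parsimony_margin = 6, seed = NULL) {
  z_matrix <- as.matrix(z_matrix)
  n <- nrow(z_matrix)
  if (n < n_folds) stop("need at least as many subjects as folds")
  if (!is.null(seed)) set.seed(seed)

  folds <- sample(rep(seq_len(n_folds), length.out = n))
  per_fold <- matrix(NA_real_, n_folds, max_C,
    dimnames = list(NULL, paste0("C", seq_len(max_C)))
  )
  for (f in seq_len(n_folds)) {
    train <- z_matrix[folds != f, , drop = FALSE]
    test <- z_matrix[folds == f, , drop = FALSE]
    if (nrow(test) == 0L) stop("fold ", f, " has no subjects")
    path <- fit_subtypes_path(train, grid, max_C,
      sd = sd,
      n_restarts = n_restarts, n_splits = n_splits
    )
    for (C in seq_len(max_C)) {
      per_fold[f, C] <- cohort_loglik(test, path[[C]])
    }
  }
  oof <- colSums(per_fold)
  cvic <- -2 * oof
  names(cvic) <- paste0("C", seq_len(max_C))
  chosen <- which.min(cvic)

  note <- NULL
  if (chosen > 1L) {
    gain <- cvic[chosen - 1L] - cvic[chosen]
    if (gain < parsimony_margin) {
      note <- sprintf(
        "CVIC improvement from C=%d to C=%d is %.2f (< margin %.2f); a more parsimonious model is defensible",
        chosen - 1L, chosen, gain, parsimony_margin
      )
    }
  }
  list(
    cvic = cvic,
    chosen = as.integer(chosen),
    oof_loglik = oof,
    per_fold = per_fold,
    folds = folds,
    note = note
  )
}
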