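# Spatial ICA for data-driven ROI discovery: group analysis mask, FastICA
# decomposition of subjects x voxels Centiloid data, z-thresholded
# component ROIs, tissue-dominance labelling, and ROI mean extraction.

#' Build the group analysis mask from tissue probability maps
#'
#' A voxel enters a participant's mask when any tissue probability (gray
#' matter, white matter or CSF) exceeds `prob_threshold`; the group mask is
#' the set of voxels included for more than `subject_fraction` of
#' participants.
#'
#' @param tissue_maps A list, one element per participant, each a
#'   `list(gm, wm, csf)` of equal-length probability vectors/arrays on one
#'   grid.
#' @param prob_threshold Per-tissue inclusion threshold (default 0.20,
#'   strict `>`).
#' @param subject_fraction Group intersection rule (default 0.5, strict
#'   `>`).
#' @return A logical vector/array of class `analysis_mask` with provenance
#'   attributes.
#' @export
build_group_mask <- function(tissue_maps, prob_threshold = 0.2,
                             subject_fraction = 0.5) {
  if (!is.list(tissue_maps) || length(tissue_maps) == 0L) {
    stop("tissue_maps must be a non-empty list of per-participant maps")
  }
  dims <- lapply(tissue_maps, function(tm) length(tm$gm))
  if (length(unique(unlist(dims))) != 1L) stop("all maps must share one grid")
  counts <- Reduce(`+`, lapply(tissue_maps, function(tm) {
    as.numeric(tm$gm > prob_threshold | tm$wm > prob_threshold |
      tm$csf > prob_threshold)
  }))
  mask <- counts / length(tissue_maps) > subject_fraction
  if (!any(mask)) stop("group mask is empty")
  dm <- dim(tissue_maps[[1]]$gm)
  if (!is.null(dm)) dim(mask) <- dm
  structure(mask,
    class = c("analysis_mask", class(mask)),
    n_subjects = length(tissue_maps),
    prob_threshold = prob_threshold,
    subject_fraction = subject_fraction
  )
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), nrow(W)) %*%
    t(e$vectors) %*% W
}

sample_skewness <- function(x) {
  xc <- x - mean(x)
  s2 <- mean(xc^2)
  if (s2 == 0) return(0)
  mean(xc^3) / s2^1.5
}

# Fixed-point FastICA with the logcosh nonlinearity and symmetric
# decorrelation, on pre-whitened data Zw (components x samples).
fastica_core <- function(Zw, seed, tol, max_iter) {
  m <- nrow(Zw)
  V <- ncol(Zw)
  set.seed(seed)
  W <- sym_decorrelate(matrix(stats::rnorm(m * m), m, m))
  for (it in seq_len(max_iter)) {
    U <- W %*% Zw
    G <- tanh(U)
    W1 <- G %*% t(Zw) / V - diag(rowMeans(1 - G^2), m) %*% W
    W1 <- sym_decorrelate(W1)
    conv <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (conv < tol) {
      return(list(W = W, converged = TRUE, iterations = it))
    }
  }
  list(W = W, converged = FALSE, iterations = max_iter)
}

#' Spatial ICA decomposition of voxel-level data
#'
#' Decomposes a subjects x voxels matrix (restricted to the analysis mask)
#' into spatially independent component maps with per-subject mixing
#' weights: rows are demeaned, whitened by PCA to exactly `n_components`,
#' and unmixed by fixed-point FastICA (logcosh, symmetric decorrelation).
#' Each map's sign is fixed so its skewness is positive (amyloid loading is
#' nonnegative). The fixed point can settle on mixed local optima, so
#' `n_runs` independent initializations are run and the solution with the
#' highest total negentropy (logcosh proxy) is kept. Deterministic given
#' the seed; non-convergent runs are retried with fresh seeds up to
#' `max_retries` before failing.
#'
#' @param X Subjects x voxels matrix (full grid or already mask-restricted),
#'   or a `synthetic_volumes` object.
#' @param mask Optional logical mask selecting the analysed voxels of `X`'s
#'   columns.
#' @param n_components Number of components (default 20).
#' @param seed Integer seed for the unmixing initialization.
#' @param n_runs Independent initializations scored by negentropy
#'   (default 3).
#' @param tol Fixed-point convergence tolerance (default 1e-4).
#' @param max_iter Maximum fixed-point iterations (default 500).
#' @param max_retries Fresh-seed retries on non-convergence (default 3).
#' @param require_convergence Reject the decomposition when no seed
#'   converges (default TRUE). With FALSE the last estimate is returned
#'   with a warning -- useful for null data with no non-Gaussian structure,
#'   where the fixed point genuinely does not settle.
#' @return An object of class `ica_result`: `maps` (components x mask
#'   voxels, unit variance), `zmaps` (mask-standardized maps), `mixing`
#'   (subjects x components), `row_means`, `mask`, `seed`.
#' @export
decompose_ica <- function(X, mask = NULL, n_components = 20, seed = 1,
                          n_runs = 3, tol = 1e-4, max_iter = 500,
                          max_retries = 3, require_convergence = TRUE) {
  if (inherits(X, "synthetic_volumes")) X <- X$data
  X <- as.matrix(X)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != ncol(X)) stop("mask length must match voxel count")
    X <- X[, mask, drop = FALSE]
  }
  n <- nrow(X)
  V <- ncol(X)
  if (!all(is.finite(X))) stop("voxel matrix must be finite")
  if (n <= n_components) {
    stop("need more subjects (", n, ") than components (", n_components, ")")
  }

  row_means <- rowMeans(X)
  Xc <- X - row_means
  cov <- tcrossprod(Xc) / (V - 1)
  e <- eigen(cov, symmetric = TRUE)
  lambda <- pmax(e$values[seq_len(n_components)], 1e-12)
  E <- e$vectors[, seq_len(n_components), drop = FALSE]
  Kw <- diag(1 / sqrt(lambda), n_components) %*% t(E)
  Zw <- Kw %*% Xc

  # negentropy proxy J = sum_i (E[log cosh(s_i)] - E[log cosh(nu)])^2 for
  # unit-variance components; higher = more non-Gaussian = better unmixing
  negentropy <- function(S) {
    sum((rowMeans(log(cosh(S))) - 0.3745672)^2)
  }
  res <- NULL
  run_seed <- seed
  for (run in seq_len(n_runs)) {
    this <- NULL
    for (try in 0:max_retries) {
      this <- fastica_core(Zw, run_seed, tol, max_iter)
      run_seed <- run_seed + 1L
      if (this$converged) break
    }
    if (this$converged) {
      this$negentropy <- negentropy(this$W %*% Zw)
      if (is.null(res) || !res$converged || this$negentropy > res$negentropy) {
        res <- this
      }
    } else if (is.null(res)) {
      res <- this
    }
  }
  if (!res$converged) {
    if (require_convergence) {
      stop("FastICA failed to converge after ", n_runs * (max_retries + 1), " seeds")
    }
    warning("FastICA did not converge; returning the last estimate")
  }
  S <- res$W %*% Zw
  A <- E %*% diag(sqrt(lambda), n_components) %*% t(res$W)

  flip <- vapply(seq_len(n_components), function(i) {
    if (sample_skewness(S[i, ]) < 0) -1 else 1
  }, numeric(1))
  S <- S * flip
  A <- sweep(A, 2, flip, "*")

  zmaps <- t(scale(t(S))) # mask-wide mean 0 / SD 1 per component

  structure(
    list(
      maps = S,
      zmaps = zmaps,
      mixing = A,
      row_means = row_means,
      mask = mask,
      n_components = n_components,
      seed = seed,
      iterations = res$iterations
    ),
    class = "ica_result"
  )
}

#' Reconstruct the (centred) data from an ICA result
#'
#' @param ica An [decompose_ica()] result.
#' @return The subjects x voxels reconstruction `mixing %*% maps` plus the
#'   row means.
#' @export
ica_reconstruct <- function(ica) {
  ica$mixing %*% ica$maps + ica$row_means
}

#' Threshold a component map into an ROI
#'
#' The map is standardized to mean 0 / SD 1 over the analysed voxels; the
#' ROI is the set of voxels with z above the threshold, intersected with
#' the gray-matter mask. One-sided thresholding follows the positive-skew
#' sign convention (amyloid loading is nonnegative).
#'
#' @param ic_map Numeric component map over the analysed voxels.
#' @param gm_mask Logical gray-matter mask over the same voxels.
#' @param z_threshold z cut-off (default 1.96).
#' @return A logical ROI vector with attribute `usable` (FALSE when the ROI
#'   is empty, with a warning).
#' @export
make_roi <- function(ic_map, gm_mask, z_threshold = 1.96) {
  ic_map <- as.numeric(ic_map)
  gm_mask <- as.logical(gm_mask)
  if (length(ic_map) != length(gm_mask)) {
    stop("map and gray-matter mask must cover the same voxels")
  }
  s <- stats::sd(ic_map)
  if (!is.finite(s) || s == 0) stop("degenerate (constant) component map")
  z <- (ic_map - mean(ic_map)) / s
  roi <- z > z_threshold & gm_mask
  usable <- any(roi)
  if (!usable) warning("empty ROI: component flagged unusable")
  structure(roi, usable = usable)
}

#' Label gray-matter-dominant components
#'
#' An algorithmic surrogate for visual IC selection: a component is
#' GM-dominant when the mean gray-matter probability over its
#' supra-threshold voxels exceeds both the mean white-matter and the mean
#' CSF probabilities there.
#'
#' @param ica An [decompose_ica()] result.
#' @param tissue Tissue probabilities `list(gm, wm, csf)` over the analysed
#'   voxels (mask-restricted automatically when the ICA carried a mask).
#' @param z_threshold Supra-threshold cut-off on the standardized map.
#' @return Logical vector (one per component) with the per-tissue mean
#'   matrix as attribute `tissue_means`.
#' @export
label_gm_dominant <- function(ica, tissue, z_threshold = 1.96) {
  gm <- as.numeric(tissue$gm)
  wm <- as.numeric(tissue$wm)
  csf <- as.numeric(tissue$csf)
  if (!is.null(ica$mask) && length(gm) == length(ica$mask)) {
    gm <- gm[ica$mask]
    wm <- wm[ica$mask]
    csf <- csf[ica$mask]
  }
  if (length(gm) != ncol(ica$zmaps)) {
    stop("tissue maps must cover the analysed voxels")
  }
  means <- t(vapply(seq_len(nrow(ica$zmaps)), function(i) {
    supra <- ica$zmaps[i, ] > z_threshold
    if (!any(supra)) return(c(gm = NA_real_, wm = NA_real_, csf = NA_real_))
    c(gm = mean(gm[supra]), wm = mean(wm[supra]), csf = mean(csf[supra]))
  }, numeric(3)))
  dominant <- !is.na(means[, "gm"]) &
    means[, "gm"] > means[, "wm"] & means[, "gm"] > means[, "csf"]
  structure(dominant, tissue_means = means)
}

#' Mean Centiloid over each ROI per subject
#'
#' @param volumes Subjects x voxels matrix (or `synthetic_volumes`); the
#'   voxel space must match the ROI masks.
#' @param roi_masks List of logical ROI vectors.
#' @return A subjects x ROI matrix of arithmetic means.
#' @export
extract_roi_means <- function(volumes, roi_masks) {
  if (inherits(volumes, "synthetic_volumes")) volumes <- volumes$data
  volumes <- as.matrix(volumes)
  if (!is.list(roi_masks)) roi_masks <- list(roi_masks)
  out <- matrix(NA_real_, nrow(volumes), length(roi_masks))
  for (j in seq_along(roi_masks)) {
    m <- as.logical(roi_masks[[j]])
    if (length(m) != ncol(volumes)) {
      stop("ROI ", j, " does not lie on the volume grid")
    }
    if (!any(m)) stop("ROI ", j, " is empty")
    out[, j] <- rowMeans(volumes[, m, drop = FALSE])
  }
  rownames(out) <- rownames(volumes)
  colnames(out) <- names(roi_masks)
  out
}

#' Pairwise overlap between ROI masks
#'
#' @param roi_masks List of logical ROI vectors on one grid.
#' @return A symmetric matrix of Jaccard overlap coefficients.
#' @export
roi_overlap <- function(roi_masks) {
  K <- length(roi_masks)
  out <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      a <- as.logical(roi_masks[[i]])
      b <- as.logical(roi_masks[[j]])
      u <- sum(a | b)
      out[i, j] <- if (u == 0) 0 else sum(a & b) / u
    }
  }
  out
}
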