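# Voxel-level fixture generator for the spatial ICA front end: smooth
# Gaussian-blob loading fields on a shared 3D grid, subject volumes as
# weighted sums of those fields, and tissue probability maps that place
# components in gray matter or CSF territory.

#' Specify the voxel-level structure of synthetic volumes
#'
#' Component maps are isotropic Gaussian blobs; each component's "true
#' mask" is its field thresholded at half maximum. Tissue probability maps
#' assign high gray-matter probability inside GM-placed blobs, high CSF
#' probability inside CSF-placed blobs, and a white-matter-dominant
#' background, summing to at most 1 per voxel.
#'
#' @param grid_dim 3D grid dimensions (default 24 x 24 x 24, 2 mm voxels).
#' @param n_components Number of spatial components K.
#' @param centers Optional K x 3 matrix of blob centres (voxel
#'   coordinates); defaults to a deterministic spread filling the grid.
#' @param sigma Blob SD in voxels (scalar recycled).
#' @param placement Per-component tissue territory, "gm" or "csf".
#' @return An object of class `volume_spec` with `component_maps` and
#'   `component_masks` (K x V matrices), `tissue` (gm/wm/csf vectors of
#'   length V), `grid_dim`.
#' @export
volume_spec <- function(grid_dim = c(24, 24, 24), n_components = 10,
                        centers = NULL, sigma = 2.5,
                        placement = rep("gm", n_components)) {
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3L || any(grid_dim < 4L)) {
    stop("grid_dim must give three dimensions of at least 4 voxels")
  }
  K <- as.integer(n_components)
  placement <- match.arg(placement, c("gm", "csf"), several.ok = TRUE)
  placement <- rep_len(placement, K)
  sigma <- rep_len(as.numeric(sigma), K)
  V <- prod(grid_dim)

  if (is.null(centers)) {
    # deterministic low-discrepancy spread over the interior of the grid
    gpos <- function(i, d) {
      frac <- ((i - 1) * c(0.618034, 0.754878, 0.569840)[d]) %% 1
      0.2 * grid_dim[d] + frac * 0.6 * grid_dim[d]
    }
    centers <- cbind(
      vapply(seq_len(K), gpos, numeric(1), d = 1L),
      vapply(seq_len(K), gpos, numeric(1), d = 2L),
      vapply(seq_len(K), gpos, numeric(1), d = 3L)
    )
  }
  centers <- matrix(centers, ncol = 3)
  if (nrow(centers) != K) stop("one centre per component is required")

  coords <- as.matrix(expand.grid(
    x = seq_len(grid_dim[1]),
    y = seq_len(grid_dim[2]),
    z = seq_len(grid_dim[3])
  ))
  maps <- matrix(0, K, V)
  for (i in seq_len(K)) {
    d2 <- rowSums(sweep(coords, 2, centers[i, ])^2)
    maps[i, ] <- exp(-d2 / (2 * sigma[i]^2))
  }
  masks <- maps >= 0.5 * apply(maps, 1, max)
  # tissue territories extend to ~3 sigma so the visible blob skirt shares
  # the tissue class of its core, not the background
  territory <- maps >= exp(-4.5) * apply(maps, 1, max)

  gm_territory <- colSums(territory[placement == "gm", , drop = FALSE]) > 0
  csf_territory <- colSums(territory[placement == "csf", , drop = FALSE]) > 0
  gm <- ifelse(gm_territory, 0.85, ifelse(csf_territory, 0.05, 0.10))
  csf <- ifelse(csf_territory, 0.85, ifelse(gm_territory, 0.05, 0.20))
  wm <- ifelse(gm_territory | csf_territory, 0.10, 0.60)

  structure(
    list(
      grid_dim = grid_dim,
      n_components = K,
      centers = centers,
      sigma = sigma,
      placement = placement,
      component_maps = maps,
      component_masks = masks,
      tissue = list(gm = gm, wm = wm, csf = csf)
    ),
    class = "volume_spec"
  )
}

#' Generate voxel-level volumes for a cohort
#'
#' Each subject's volume is a weighted sum of the component fields plus
#' spatially white noise; the weights solve a K x K linear system so that,
#' at zero noise, the mean over each component's true mask equals the
#' subject's Centiloid value for that component.
#'
#' @param cohort A [generate_cohort()] result, a harmonized record table,
#'   or a numeric subjects x K Centiloid matrix.
#' @param spec A [volume_spec()] whose component count matches K.
#' @param noise_sd SD of additive voxel noise (Centiloid units).
#' @param seed Integer seed for the noise.
#' @return An object of class `synthetic_volumes`: `data` (subjects x V
#'   matrix), the spec, and per-subject tissue maps (shared).
#' @export
generate_volumes <- function(cohort, spec, noise_sd = 0, seed = 1) {
  if (!inherits(spec, "volume_spec")) stop("spec must be a volume_spec")
  cl <- if (inherits(cohort, "synthetic_cohort")) {
    harm <- harmonize_records(cohort$records)
    as.matrix(harm[, roi_columns(harm)])
  } else if (is.data.frame(cohort)) {
    harm <- harmonize_records(cohort)
    as.matrix(harm[, roi_columns(harm)])
  } else {
    as.matrix(cohort)
  }
  K <- spec$n_components
  if (ncol(cl) != K) {
    stop("component count (", K, ") must equal the biomarker count (", ncol(cl), ")")
  }
  # A[j, i] = mean of component i's field over component j's true mask
  A <- matrix(0, K, K)
  for (j in seq_len(K)) {
    A[j, ] <- rowMeans(spec$component_maps[, spec$component_masks[j, ], drop = FALSE])
  }
  W <- t(solve(A, t(cl))) # subjects x K weights
  set.seed(seed)
  X <- W %*% spec$component_maps
  if (noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), ncol(X))
  }
  rownames(X) <- rownames(cl)
  structure(
    list(
      data = X,
      weights = W,
      spec = spec,
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "synthetic_volumes"
  )
}

#' Shared tissue probability maps replicated per subject
#'
#' @param spec A [volume_spec()].
#' @param n_subjects Number of subjects.
#' @return A list of length `n_subjects`, each `list(gm, wm, csf)`.
#' @export
subject_tissue_maps <- function(spec, n_subjects) {
  rep(list(spec$tissue), n_subjects)
}

#' Extract one subject's volume as a 3D array
#'
#' @param volumes A [generate_volumes()] result.
#' @param i Subject index.
#' @return A 3D numeric array on the spec's grid.
#' @export
as_volume_array <- function(volumes, i) {
  array(volumes$data[i, ], dim = volumes$spec$grid_dim)
}
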