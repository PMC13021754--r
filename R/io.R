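# Format plumbing: provenance-stamped CSV, NIfTI volumes/masks, and JSON
# model serialization.

# jsonlite simplifies a list of equal-length vectors to a matrix with one
# row per element; undo that when restoring ordering lists.
as_ordering_list <- function(x) {
  if (is.matrix(x)) {
    lapply(seq_len(nrow(x)), function(i) x[i, ])
  } else if (!is.list(x)) {
    list(x)
  } else {
    x
  }
}

hash_object <- function(x) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write / read a table as CSV with a provenance header
#'
#' Provenance (stage, seed, config hash) is stored in leading `#` comment
#' lines; the reader validates the field count of every line and names the
#' first malformed line.
#'
#' @param x Data frame to write.
#' @param path CSV path.
#' @param stage,seed,config_hash Provenance fields.
#' @return The path (writer, invisibly) or the data frame with a
#'   `provenance` attribute (reader).
#' @export
write_table_csv <- function(x, path, stage = "unspecified", seed = NA,
                            config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# provenance: stage=%s seed=%s config_hash=%s package=amysustain %s",
    stage, seed, config_hash, as.character(utils::packageVersion("amysustain"))
  ), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  body_idx <- which(!grepl("^#", lines))
  body <- lines[body_idx]
  if (length(body) < 1L) stop("no data rows in ", path)
  nfield <- vapply(strsplit(body, ",", fixed = TRUE), length, integer(1))
  bad <- which(nfield != nfield[1])
  if (length(bad) > 0L) {
    stop(
      "malformed CSV ", path, ": line ", body_idx[bad[1]],
      " has ", nfield[bad[1]], " fields, expected ", nfield[1]
    )
  }
  out <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  attr(out, "provenance") <- prov
  out
}

nifti_affine <- function(voxel_mm = 2) {
  diag(c(rep(voxel_mm, 3), 1))
}

#' Write / read a 3D volume or mask as NIfTI
#'
#' Identity orientation scaled to 2 mm isotropic voxels.
#'
#' @param x 3D numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Isotropic voxel size in mm.
#' @return The path (writer, invisibly); the reader returns the array.
#' @export
write_volume_nifti <- function(x, path, voxel_mm = 2) {
  img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
  img <- RNifti::`sform<-`(img, structure(nifti_affine(voxel_mm), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write / read a mask stack as integer-labelled NIfTI plus a JSON manifest
#'
#' ROI k contributes label k; overlapping voxels keep the lowest label.
#'
#' @param roi_masks List of logical masks sharing one 3D grid.
#' @param dim3 Grid dimensions.
#' @param path NIfTI path; the manifest goes to `<path>.json`.
#' @return Paths (invisibly); the reader returns the list of masks.
#' @export
write_roi_nifti <- function(roi_masks, dim3, path) {
  lab <- integer(prod(dim3))
  for (k in rev(seq_along(roi_masks))) {
    lab[as.logical(roi_masks[[k]])] <- k
  }
  write_volume_nifti(array(lab, dim = dim3), path)
  jsonlite::write_json(
    list(
      n_rois = length(roi_masks),
      names = if (is.null(names(roi_masks))) {
        sprintf("roi_%d", seq_along(roi_masks))
      } else {
        names(roi_masks)
      },
      dim = dim3,
      voxels = vapply(roi_masks, function(m) sum(as.logical(m)), integer(1))
    ),
    paste0(path, ".json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(c(path, paste0(path, ".json")))
}

#' @rdname write_roi_nifti
#' @export
read_roi_nifti <- function(path) {
  lab <- read_volume_nifti(path)
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  masks <- lapply(seq_len(manifest$n_rois), function(k) as.vector(lab == k))
  names(masks) <- manifest$names
  masks
}

#' Serialize / restore a subtype model as JSON
#'
#' Orderings are stored as event-name lists together with the grid,
#' fractions, SDs and fit metadata.
#'
#' @param model A [subtype_model()].
#' @param path JSON path.
#' @return The path (writer, invisibly); the reader returns the model.
#' @export
write_model_json <- function(model, path) {
  grid <- model$grid
  jsonlite::write_json(
    list(
      biomarkers = grid$biomarkers,
      thresholds = grid$thresholds,
      z_max = grid$z_max,
      orderings = lapply(model$orderings, function(o) grid$events$name[o]),
      fractions = model$fractions,
      sd = model$sd,
      loglik = model$loglik
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- event_grid(x$biomarkers, x$thresholds, x$z_max)
  orderings <- lapply(as_ordering_list(x$orderings), function(nm) {
    match(nm, grid$events$name)
  })
  m <- subtype_model(grid, orderings, x$fractions, x$sd)
  m$loglik <- x$loglik
  m
}
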