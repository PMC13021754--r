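#' Define the biomarker-by-threshold event grid
#'
#' A z-score event is the crossing of one control-referenced threshold by one
#' regional biomarker. With K biomarkers and per-biomarker thresholds
#' (default 1, 2 and 3 control standard deviations) the model has
#' N = sum of threshold counts events, and subjects occupy integer stages
#' 0..N (stage k = the first k events of an ordering have occurred).
#'
#' @param biomarkers Character vector of biomarker (region) names, or a
#'   single integer giving the number of biomarkers (named `roi_1`, ...).
#' @param thresholds Numeric vector of z-thresholds shared by all biomarkers
#'   (strictly increasing, positive), or a named list with one such vector
#'   per biomarker.
#' @param z_max Plateau z-value reached at the final stage (default 5).
#'
#' @return An object of class `event_grid` with fields `biomarkers`,
#'   `thresholds`, `z_max`, `n_events`, and an `events` data frame
#'   (`event`, `biomarker` index, `level`, `name`).
#' @export
event_grid <- function(biomarkers, thresholds = c(1, 2, 3), z_max = 5) {
  if (is.numeric(biomarkers) && length(biomarkers) == 1L) {
    biomarkers <- sprintf("roi_%d", seq_len(biomarkers))
  }
  biomarkers <- as.character(biomarkers)
  K <- length(biomarkers)
  if (K < 1L) stop("at least one biomarker is required")
  if (anyDuplicated(biomarkers)) stop("biomarker names must be unique")

  if (!is.list(thresholds)) {
    thresholds <- stats::setNames(rep(list(as.numeric(thresholds)), K), biomarkers)
  } else {
    if (!setequal(names(thresholds), biomarkers)) {
      stop("threshold list must be named by biomarker")
    }
    thresholds <- thresholds[biomarkers]
  }
  for (bm in biomarkers) {
    th <- thresholds[[bm]]
    if (length(th) < 1L || any(!is.finite(th)) || any(th <= 0)) {
      stop("thresholds must be positive and finite")
    }
    if (is.unsorted(th, strictly = TRUE)) {
      stop("thresholds must be strictly increasing")
    }
    if (any(th >= z_max)) stop("thresholds must lie below z_max")
  }

  events <- do.call(rbind, lapply(seq_len(K), function(i) {
    data.frame(
      biomarker = i,
      level = thresholds[[biomarkers[i]]],
      stringsAsFactors = FALSE
    )
  }))
  events$event <- seq_len(nrow(events))
  events$name <- sprintf("%s:z%g", biomarkers[events$biomarker], events$level)
  events <- events[, c("event", "biomarker", "level", "name")]

  structure(
    list(
      biomarkers = biomarkers,
      thresholds = thresholds,
      z_max = as.numeric(z_max),
      n_events = nrow(events),
      events = events
    ),
    class = "event_grid"
  )
}

#' @export
print.event_grid <- function(x, ...) {
  cat(sprintf(
    "Event grid: %d biomarkers x thresholds -> %d events (stages 0..%d), z_max = %g\n",
    length(x$biomarkers), x$n_events, x$n_events, x$z_max
  ))
  invisible(x)
}

check_ordering <- function(grid, ordering) {
  N <- grid$n_events
  ordering <- as.integer(ordering)
  if (length(ordering) != N || !setequal(ordering, seq_len(N))) {
    stop("ordering must be a permutation of all ", N, " events")
  }
  ordering
}

#' Random event ordering with within-biomarker threshold order
#'
#' Draws a uniformly random interleaving of the biomarkers' event chains in
#' which each biomarker's z = 1 event precedes its z = 2 event precedes its
#' z = 3 event (the physically meaningful orderings a progressive disease
#' can generate). The search and sampler over orderings do not enforce this
#' constraint; the generative truth does.
#'
#' @param grid An [event_grid()].
#' @return An integer event permutation.
#' @export
sample_ordering <- function(grid) {
  enforce_monotone(grid, sample.int(grid$n_events))
}

# Restore within-biomarker threshold order while keeping each biomarker's
# set of stage positions fixed.
enforce_monotone <- function(grid, ordering) {
  ordering <- check_ordering(grid, ordering)
  pos <- match(seq_len(grid$n_events), ordering)
  for (b in unique(grid$events$biomarker)) {
    idx <- which(grid$events$biomarker == b) # ascending threshold order
    pos[idx] <- sort(pos[idx])
  }
  order(pos)
}

#' Reverse a progression pattern
#'
#' Reverses the biomarker interleaving of an ordering (the last biomarker
#' events become the earliest) while restoring within-biomarker threshold
#' order, giving a maximally dissimilar but still physically valid
#' progression.
#'
#' @param grid An [event_grid()].
#' @param ordering An event permutation.
#' @return The reversed valid permutation.
#' @export
reverse_ordering <- function(grid, ordering) {
  enforce_monotone(grid, rev(check_ordering(grid, ordering)))
}

#' Expected z-value along a progression trajectory
#'
#' The expected z-score of a biomarker at a given stage under one event
#' ordering: 0 at stage 0, exactly the threshold value at the stage position
#' of each of the biomarker's events, linear in between, and rising linearly
#' from the last threshold to `z_max` at stage N. Stage N always evaluates
#' to `z_max`. Real-valued stages are linearly interpolated.
#'
#' @param grid An [event_grid()].
#' @param ordering Integer permutation of the grid's events (event ids by
#'   stage position).
#' @param biomarker Biomarker name or index.
#' @param stage Numeric vector of stages in `[0, N]`.
#' @return Numeric vector of expected z-values.
#' @export
trajectory_value <- function(grid, ordering, biomarker, stage) {
  ordering <- check_ordering(grid, ordering)
  if (is.character(biomarker)) {
    biomarker <- match(biomarker, grid$biomarkers)
  }
  if (is.na(biomarker) || biomarker < 1 || biomarker > length(grid$biomarkers)) {
    stop("unknown biomarker")
  }
  N <- grid$n_events
  if (any(stage < 0 | stage > N)) stop("stage must lie in [0, N]")

  pos <- match(seq_len(N), ordering)
  idx <- which(grid$events$biomarker == biomarker)
  if (length(idx) == 0L) stop("biomarker has no events in the ordering")
  p <- pos[idx]
  z <- grid$events$level[idx]
  o <- order(p)
  xs <- c(0, p[o])
  ys <- c(0, z[o])
  if (max(p) < N) {
    xs <- c(xs, N)
    ys <- c(ys, grid$z_max)
  }
  out <- stats::approx(xs, ys, xout = pmin(stage, max(xs)), rule = 2)$y
  out[stage == N] <- grid$z_max
  out
}

#' Trajectory matrix for all biomarkers at integer stages
#'
#' @param grid An [event_grid()].
#' @param ordering Integer permutation of the grid's events.
#' @return A K x (N+1) matrix of expected z-values; columns are stages 0..N.
#' @export
trajectory_matrix <- function(grid, ordering) {
  ordering <- check_ordering(grid, ordering)
  T <- traj_matrix_cpp(
    grid$events$biomarker, grid$events$level, ordering,
    length(grid$biomarkers), grid$z_max
  )
  dimnames(T) <- list(grid$biomarkers, as.character(0:grid$n_events))
  T
}
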