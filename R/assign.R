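# Subject-level assignment, positional variance diagrams, and longitudinal
# stability accounting.

#' Assign subjects to subtype and stage
#'
#' Maximum a posteriori stage (marginalized over subtypes) and subtype
#' (marginalized over stages) under a fitted model with a uniform stage
#' prior. Subjects whose MAP stage is 0 carry no subtype (`ml_subtype` is
#' `NA`); the stage-unrestricted subtype argmax is reported alongside. Ties
#' resolve to the lowest index.
#'
#' @param z_matrix Numeric n x K matrix of z-scores (rows may be named by
#'   subject).
#' @param model A fitted [subtype_model()].
#' @param subject_id Optional subject identifiers (defaults to rownames).
#' @param visit Visit label stored with the assignments.
#' @param warn_ties Message when posterior ties were broken (default TRUE).
#' @return A data frame with `subject_id`, `visit`, `ml_stage`,
#'   `ml_subtype`, `subtype_prob` (max stage-marginalized subtype posterior),
#'   `expected_stage`, `ml_subtype_unrestricted`, and `log_marginal`.
#' @export
assign_subjects <- function(z_matrix, model, subject_id = NULL,
                            visit = "baseline", warn_ties = TRUE) {
  z_matrix <- as.matrix(z_matrix)
  n <- nrow(z_matrix)
  if (is.null(subject_id)) {
    subject_id <- rownames(z_matrix)
    if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(n))
  }
  grid <- model$grid
  N <- grid$n_events
  C <- model$n_subtypes

  logA <- lapply(seq_len(C), function(cc) {
    L <- stage_loglik_matrix(z_matrix, grid, model$orderings[[cc]], model$sd)
    L + log(model$fractions[cc]) - log(N + 1)
  })
  # log stage-marginal (over subtypes) and log subtype-marginal (over stages)
  stage_m <- Reduce(function(a, b) {
    m <- pmax(a, b)
    m + log(exp(a - m) + exp(b - m))
  }, logA)
  sub_m <- vapply(logA, row_logsumexp, numeric(n))
  sub_m <- matrix(sub_m, nrow = n)
  lm <- row_logsumexp(sub_m)

  p_stage <- exp(stage_m - lm)
  p_sub <- exp(sub_m - lm)

  ml_stage <- max.col(p_stage, ties.method = "first") - 1L
  ml_sub_any <- max.col(p_sub, ties.method = "first")
  sub_prob <- p_sub[cbind(seq_len(n), ml_sub_any)]
  if (warn_ties) {
    ties <- sum(rowSums(abs(p_sub - sub_prob) < 1e-12) > 1L)
    if (ties > 0L) {
      message(ties, " subtype posterior tie(s) resolved to the lowest index")
    }
  }
  ml_subtype <- ifelse(ml_stage == 0L, NA_integer_, ml_sub_any)

  data.frame(
    subject_id = as.character(subject_id),
    visit = visit,
    ml_stage = ml_stage,
    ml_subtype = as.integer(ml_subtype),
    subtype_prob = sub_prob,
    expected_stage = as.numeric(p_stage %*% (0:N)),
    ml_subtype_unrestricted = ml_sub_any,
    log_marginal = lm,
    stringsAsFactors = FALSE
  )
}

#' Positional variance diagram from MCMC samples
#'
#' For each subtype, the frequency with which each event occupies each stage
#' position across the retained MCMC samples. Every event's row sums to 1.
#'
#' @param samples An [mcmc_sample()] result with at least one kept sample.
#' @return An object of class `pvd`: a list `freq` of events x positions
#'   matrices (one per subtype), plus the grid and sample count.
#' @export
build_pvd <- function(samples) {
  if (!inherits(samples, "mcmc_samples")) stop("samples must be mcmc_samples")
  if (samples$n_kept < 1L) stop("no post-burn-in samples available")
  grid <- samples$grid
  N <- grid$n_events
  C <- dim(samples$orderings)[2]
  freq <- vector("list", C)
  for (cc in seq_len(C)) {
    ev <- as.vector(samples$orderings[, cc, ])
    po <- rep(seq_len(N), samples$n_kept)
    tab <- table(
      factor(ev, levels = seq_len(N)),
      factor(po, levels = seq_len(N))
    )
    m <- unclass(tab) / samples$n_kept
    dimnames(m) <- list(grid$events$name, as.character(seq_len(N)))
    freq[[cc]] <- m
  }
  structure(
    list(freq = freq, grid = grid, n_samples = samples$n_kept),
    class = "pvd"
  )
}

as_pvd_matrix <- function(x) {
  if (inherits(x, "pvd")) {
    if (length(x$freq) != 1L) {
      stop("pass a single positional-frequency matrix (e.g. pvd$freq[[c]])")
    }
    return(x$freq[[1L]])
  }
  as.matrix(x)
}

#' Pearson similarity between two positional variance diagrams
#'
#' Pearson correlation between the flattened positional-frequency matrices
#' of two progression patterns over the same event grid.
#'
#' @param a,b Positional-frequency matrices (events x positions), or
#'   single-subtype `pvd` objects.
#' @return A list with `r` and `p`; both `NA` (with a warning) when either
#'   matrix has zero variance.
#' @export
pvd_correlation <- function(a, b) {
  a <- as_pvd_matrix(a)
  b <- as_pvd_matrix(b)
  if (!all(dim(a) == dim(b))) stop("positional matrices must share the event grid")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance positional matrix: correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(as.numeric(a), as.numeric(b))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Apply a frozen baseline model to follow-up scans
#'
#' Follow-up records are harmonized and z-scored through the same control
#' model fitted at baseline (no refitting of any component) and assigned
#' with the frozen progression model. Follow-up age enters the frozen
#' residualization.
#'
#' @param model The baseline [subtype_model()].
#' @param followup_records Follow-up record table (SUVR scale).
#' @param control_model The baseline [fit_control_model()] result.
#' @param calibrations Tracer calibration table.
#' @param baseline_ids Optional baseline subject ids; follow-up subjects
#'   absent at baseline still get assignments but trigger a warning for
#'   paired analyses.
#' @return Assignments as from [assign_subjects()], with `visit` taken from
#'   the records.
#' @export
apply_longitudinal <- function(model, followup_records, control_model,
                               calibrations = tracer_calibrations(),
                               baseline_ids = NULL) {
  harm <- harmonize_records(followup_records, calibrations)
  z <- zscore_records(harm, control_model)
  visit <- if ("visit" %in% names(followup_records)) {
    followup_records$visit
  } else {
    "followup"
  }
  res <- assign_subjects(z, model,
    subject_id = followup_records$subject_id,
    visit = visit, warn_ties = FALSE
  )
  if (!is.null(baseline_ids)) {
    unpaired <- setdiff(res$subject_id, baseline_ids)
    if (length(unpaired) > 0L) {
      warning(
        length(unpaired),
        " follow-up subject(s) absent at baseline; excluded from paired stability metrics"
      )
    }
    attr(res, "unpaired") <- unpaired
  }
  res
}

assignment_category <- function(assignments) {
  ifelse(assignments$ml_stage == 0L, "stage0",
    paste0("subtype", assignments$ml_subtype)
  )
}

#' Longitudinal subtype and stage stability metrics
#'
#' Pairs baseline and follow-up assignments by subject and tabulates:
#' maintained category (same subtype, with Stage 0 -> Stage 0 counted as
#' maintained), Stage 0 -> higher stage, subtype changes, reversions to
#' Stage 0 per subtype, and stage agreement (same / progressed / regressed).
#' Unpaired subjects are excluded and counted.
#'
#' @param baseline,followup Assignment tables from [assign_subjects()].
#' @return An object of class `stability_report`.
#' @export
stability_metrics <- function(baseline, followup) {
  b <- baseline[, c("subject_id", "ml_stage", "ml_subtype")]
  f <- followup[, c("subject_id", "ml_stage", "ml_subtype")]
  names(b)[2:3] <- c("stage_b", "subtype_b")
  names(f)[2:3] <- c("stage_f", "subtype_f")
  m <- merge(b, f, by = "subject_id")
  n <- nrow(m)
  if (n == 0L) stop("no paired subjects")

  cat_b <- ifelse(m$stage_b == 0L, "stage0", paste0("subtype", m$subtype_b))
  cat_f <- ifelse(m$stage_f == 0L, "stage0", paste0("subtype", m$subtype_f))

  maintained <- cat_b == cat_f
  stage0_up <- m$stage_b == 0L & m$stage_f > 0L
  sub_changed <- m$stage_b > 0L & m$stage_f > 0L & m$subtype_b != m$subtype_f
  to_stage0 <- m$stage_b > 0L & m$stage_f == 0L

  subtypes <- sort(unique(m$subtype_b[!is.na(m$subtype_b)]))
  to_stage0_by <- vapply(subtypes, function(s) {
    sum(to_stage0 & m$subtype_b == s, na.rm = TRUE)
  }, integer(1))
  names(to_stage0_by) <- paste0("subtype", subtypes)

  maintained_by <- table(cat_b[maintained])

  stage_cat <- ifelse(m$stage_f == m$stage_b, "same",
    ifelse(m$stage_f > m$stage_b, "progressed", "regressed")
  )
  stage_tab <- vapply(
    c("same", "progressed", "regressed"),
    function(k) sum(stage_cat == k), integer(1)
  )

  pct <- function(x) 100 * x / n
  structure(
    list(
      n_paired = n,
      n_unpaired_baseline = sum(!b$subject_id %in% f$subject_id),
      n_unpaired_followup = sum(!f$subject_id %in% b$subject_id),
      maintained = list(
        count = sum(maintained), pct = pct(sum(maintained)),
        by_category = maintained_by
      ),
      stage0_to_higher = list(count = sum(stage0_up), pct = pct(sum(stage0_up))),
      subtype_changed = list(
        count = sum(sub_changed, na.rm = TRUE),
        pct = pct(sum(sub_changed, na.rm = TRUE))
      ),
      subtype_to_stage0 = to_stage0_by,
      stage = data.frame(
        category = names(stage_tab),
        count = as.integer(stage_tab),
        pct = pct(as.integer(stage_tab)),
        stringsAsFactors = FALSE
      ),
      transitions = table(baseline = cat_b, followup = cat_f)
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability over %d paired subjects:\n", x$n_paired))
  cat(sprintf(
    "  maintained category: %d (%.1f%%)\n",
    x$maintained$count, x$maintained$pct
  ))
  cat(sprintf(
    "  stage 0 -> higher:  %d (%.1f%%)\n",
    x$stage0_to_higher$count, x$stage0_to_higher$pct
  ))
  cat(sprintf(
    "  subtype changed:    %d (%.1f%%)\n",
    x$subtype_changed$count, x$subtype_changed$pct
  ))
  for (i in seq_len(nrow(x$stage))) {
    cat(sprintf(
      "  stage %-10s    %d (%.1f%%)\n",
      paste0(x$stage$category[i], ":"), x$stage$count[i], x$stage$pct[i]
    ))
  }
  invisible(x)
}

#' Annualized per-subject change rates
#'
#' (follow-up - baseline) / interval in years (exact day counts / 365.25)
#' for the requested measures. Pairs with a zero or negative interval are
#' rejected with a warning.
#'
#' @param baseline,followup Record tables sharing `subject_id`; the
#'   follow-up table must carry `interval_days`.
#' @param measures Column names to difference (present in both tables).
#' @return A data frame with `subject_id`, `interval_days`, and one
#'   `rate_<measure>` column per measure (units per year).
#' @export
summarize_rates <- function(baseline, followup,
                            measures = c("whole_brain_centiloid", "adas13")) {
  if (!"interval_days" %in% names(followup)) {
    stop("follow-up records must carry interval_days")
  }
  missing_cols <- setdiff(measures, intersect(names(baseline), names(followup)))
  if (length(missing_cols) > 0L) {
    stop("measure(s) absent from records: ", paste(missing_cols, collapse = ", "))
  }
  b <- baseline[, c("subject_id", measures)]
  names(b)[-1] <- paste0(measures, "_b")
  f <- followup[, c("subject_id", "interval_days", measures)]
  m <- merge(b, f, by = "subject_id")
  bad <- !is.finite(m$interval_days) | m$interval_days <= 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) rejected for zero/negative interval")
    m <- m[!bad, , drop = FALSE]
  }
  years <- m$interval_days / 365.25
  out <- data.frame(
    subject_id = m$subject_id,
    interval_days = m$interval_days,
    stringsAsFactors = FALSE
  )
  for (me in measures) {
    out[[paste0("rate_", me)]] <- (m[[me]] - m[[paste0(me, "_b")]]) / years
  }
  out
}
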