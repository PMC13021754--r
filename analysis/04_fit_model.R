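#!/usr/bin/env Rscript
# Subtype-count selection by ten-fold CVIC, hierarchical fitting of the
# subtype-and-stage model, MCMC sampling of ordering uncertainty, and
# positional variance diagrams (magenta/green/cyan = z 1/2/3).

library(amysustain)

state <- readRDS("results/cohort/state.rds")
hstate <- readRDS("results/harmonized/state.rds")
out <- "results/model"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260924

z <- hstate$z[!state$cohort$subjects$is_control, ]
grid <- state$truth$grid

cv <- cvic_select(z, grid,
  max_C = 3, n_folds = 10, n_restarts = 1, n_splits = 0, seed = seed
)
write_table_csv(
  data.frame(C = seq_along(cv$cvic), cvic = as.numeric(cv$cvic)),
  file.path(out, "cvic.csv"), "select"
)
cat("CVIC by number of subtypes:", paste(round(cv$cvic, 1), collapse = ", "), "\n")
cat("Selected C =", cv$chosen, if (!is.null(cv$note)) paste0("(", cv$note, ")") else "", "\n")

model <- fit_subtypes(z, grid, cv$chosen, n_restarts = 2, seed = seed + 1)
write_model_json(model, file.path(out, "model.json"))
cat(sprintf(
  "Fitted %d-subtype model: loglik %.1f, fractions %s.\n",
  model$n_subtypes, model$loglik,
  paste(sprintf("%.2f", model$fractions), collapse = " / ")
))

samples <- mcmc_sample(z, model, n_iter = 20000, seed = seed + 2)
pvd <- build_pvd(samples)
for (cc in seq_along(pvd$freq)) {
  write_table_csv(
    as.data.frame(pvd$freq[[cc]]),
    file.path(out, sprintf("pvd_subtype%d.csv", cc)), "mcmc"
  )
  plot_pvd(pvd, cc, file = file.path(out, sprintf("pvd_subtype%d.png", cc)))
}
plot_loglik_trace(samples, file.path(out, "mcmc_trace.png"))
saveRDS(list(cv = cv, model = model, samples = samples, pvd = pvd),
  file.path(out, "state.rds")
)

# similarity of progression patterns between subtypes
if (model$n_subtypes > 1) {
  for (i in 1:(model$n_subtypes - 1)) {
    for (j in (i + 1):model$n_subtypes) {
      r <- pvd_correlation(pvd$freq[[i]], pvd$freq[[j]])
      cat(sprintf("PVD similarity subtype %d vs %d: r = %.3f (p = %.2g)\n", i, j, r$r, r$p))
    }
  }
}
cat(sprintf("MCMC ordering acceptance rate: %.2f\n", samples$acceptance[["ordering"]]))
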