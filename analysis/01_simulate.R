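#!/usr/bin/env Rscript
# Simulate the study cohort: a three-subtype amyloid progression ground
# truth over 10 ICA-like regions (events at 1/2/3 control SD, 30 stages),
# a baseline cohort of progressors plus designed controls, and follow-up
# scans ~915 +/- 431 days later. Writes records (SUVR scale) and the latent
# truth under results/cohort/.

library(amysustain)

seed <- 20260924
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- synthetic_truth(
  n_biomarkers = 10, n_subtypes = 3, noise_sd = 0.7,
  fractions = c(0.4, 0.35, 0.25), seed = seed
)
cohort <- generate_cohort(truth, n_subjects = 700, n_controls = 300, seed = seed)
followup <- generate_followup(cohort, truth, seed = seed + 1)

write_cohort(cohort, out)
write_table_csv(followup$records, file.path(out, "followup.csv"),
  stage = "simulate", seed = seed
)
saveRDS(
  list(truth = truth, cohort = cohort, followup = followup),
  file.path(out, "state.rds")
)

cat(sprintf(
  "Simulated %d baseline scans (%d designed controls) and %d follow-ups.\n",
  nrow(cohort$records), sum(cohort$subjects$is_control), nrow(followup$records)
))
cat(sprintf(
  "True subtype mix among staged progressors: %s.\n",
  paste(table(cohort$subjects$true_subtype), collapse = " / ")
))
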