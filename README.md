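# amysustain

Subtype and stage inference for spatiotemporal amyloid-beta progression
from cross-sectional PET data.

## The problem

Amyloid PET is usually reduced to one global burden number, but the
*spatial pattern* of deposition differs between individuals and predicts
different clinical courses. `amysustain` models that heterogeneity from a
single cross-sectional visit per subject: it harmonizes tracer-specific
SUVR to the Centiloid scale, discovers regions of interest by spatial ICA,
anchors every measurement to a normative control group, and then fits a
**z-score event-based subtype-and-stage model** — a mixture of event
orderings in which each regional biomarker crossing 1, 2 and 3 control
standard deviations is one event, a *subtype* is an ordering of all
K × 3 events, and a subject's *stage* is the number of events that have
occurred (0..N, N = 30 for K = 10 regions).

For biomarker *i* at stage *k* under ordering *S*, the expected z-value
g<sub>i</sub>(k | S) is piecewise linear through the thresholds at their
event positions, plateauing at z<sub>max</sub> = 5 at stage N; the data
likelihood is a product of Gaussians around that trajectory, marginalized
uniformly over stages and mixed over subtypes. Fitting uses greedy
single-event relocation with data-driven warm starts, hierarchical
cluster-splitting EM for the mixture, Metropolis–Hastings MCMC for
ordering uncertainty (positional variance diagrams), and a ten-fold
cross-validation information criterion (CVIC) for the number of subtypes.
A frozen baseline model applied to follow-up scans quantifies subtype and
stage stability.

A fully seeded synthetic-cohort generator (`synthetic_truth()`,
`generate_cohort()`, `generate_followup()`, `generate_volumes()`) inverts
the model so every stage of the pipeline is testable against known ground
truth — including the voxel-level ICA front end.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
three-subtype cohort (1,000 baseline scans, 10 regions, 30 stages,
follow-up after ~915 ± 431 days):

```sh
Rscript analysis/01_simulate.R        # cohort + follow-up + ground truth
Rscript analysis/02_harmonize.R       # Centiloid, controls, z-scores
Rscript analysis/03_ica_rois.R        # voxel ICA front end (24^3 grid)
Rscript analysis/04_fit_model.R       # CVIC, fit, MCMC, PVDs
Rscript analysis/05_assign_validate.R # assignment + longitudinal stability
```

Output from one run (seed 20260924):

```
275 of 1000 scans amyloid-positive; 389 normative controls retained.
Control z calibration: mean 0.000, SD 1.000 (across regions).
Component-to-source spatial |correlation|: min 0.982, median 0.988.
CVIC by number of subtypes: 22586.6, 21459.3, 21146.9
Selected C = 3
Fitted 3-subtype model: loglik -10533.1, fractions 0.27 / 0.38 / 0.35.
Baseline: 49 Stage 0 (no subtype); subtype sizes 163 / 266 / 222.
Recovery: mid-course subtype accuracy 93.8%; stage Spearman rho 0.983.
Stability over 1000 paired subjects:
  maintained category: 641 (64.1%)
  stage progressed:    649 (64.9%)
Annualized amyloid accrual: mean 2.0 CL/yr over 1000 pairs.
```

Reading this: the control regressions calibrate exactly (z ≈ N(0, 1) on
controls); the ICA recovers the planted spatial sources almost perfectly;
CVIC correctly prefers the generating three-subtype model; subjects in the
informative mid-course stages are assigned to their true subtype 94% of
the time and inferred stages track true stages at ρ = 0.98; and under the
generator's Poisson stage-progression law most subjects advance at
follow-up while their subtype label is stable. PVD heatmaps
(magenta/green/cyan = z 1/2/3) land in `results/model/`.

The same machinery is available as one call on a record table:

```r
library(amysustain)
cfg <- pipeline_config(records, followup = followup_records,
                       output_dir = "results/run1", seed = 1)
res <- run_pipeline(cfg)   # harmonize -> zscore -> select -> fit -> mcmc
res$stability              #   -> assign -> longitudinal, with a manifest
```

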