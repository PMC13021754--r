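Package: amysustain
Title: Subtype and Stage Inference for Spatiotemporal Amyloid PET Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the spatiotemporal progression of amyloid-beta deposition
    from cross-sectional PET data. Provides Centiloid harmonization of
    florbetapir and florbetaben SUVR measurements, control-anchored z-scoring
    with age and sex residualization, spatial independent component analysis
    for data-driven region-of-interest discovery, a z-score event-based
    subtype-and-stage mixture model with greedy maximum-likelihood ordering
    search, Markov chain Monte Carlo uncertainty estimation, positional
    variance diagrams, cross-validated selection of the number of subtypes,
    and longitudinal subtype/stage stability metrics. A synthetic-cohort
    generator with known ground truth supports end-to-end validation without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
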