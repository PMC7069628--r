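Package: periospec
Title: MALDI-TOF Protein Profiling Diagnostics for Periodontitis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for diagnosing periodontitis from linear-mode
    MALDI-TOF protein profiles of saliva, gingival crevicular fluid and dental
    plaque. Implements per-spectrum preprocessing (quality control, moving
    average smoothing, SNIP baseline estimation, total-ion-current
    normalisation, MAD-based peak picking, quadratic warping alignment and
    technical-replicate averaging into main spectrum profiles), peak binning
    into sample-by-peak intensity matrices, Wilcoxon peak screening, binary
    discriminant peak ranking, gain-ratio decision trees with stratified
    k-fold cross-validation, majority-vote fusion of per-specimen predictions
    with exact binomial confidence intervals, cohort summary statistics, and a
    seeded synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    mzR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classifier.R'
    'epistats.R'
    'features.R'
    'fusion.R'
    'io.R'
    'methods.R'
    'periospec-package.R'
    'pipeline.R'
    'preprocess.R'
    'simulate.R'
    'utils.R'
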