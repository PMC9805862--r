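Package: crossfc
Title: Resting-State Functional Connectivity Density and Crossover Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for placebo-controlled crossover resting-state
    fMRI trials. Provides nuisance regression (CompCor components, 12 motion
    regressors, linear trend, motion/intensity scrubbing), zero-phase 0.01-0.1 Hz
    band-pass filtering, global functional connectivity density (gFCD) hub
    mapping with K/K0 normalization, seed-based connectivity with Fisher-z
    transform, Gaussian smoothing of derived maps, and group-level inference
    for the 2x2 within-subject time-by-drug interaction with age and sequence
    covariates, including sign-flip permutation cluster-level FWE correction and
    post hoc paired tests. Includes a synthetic cohort generator with planted
    hubs, seed-target coupling, a planted interaction, tissue nuisance signals
    and motion spikes, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
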