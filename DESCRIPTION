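Package: phaseConn
Title: Phase-Lag EEG Connectivity with Trait Moderation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for volume-conduction-robust EEG phase-synchrony analysis
    of emotion-regulation experiments. Implements DPSS multitaper
    cross-spectral estimation, the debiased weighted Phase Lag Index (wPLI)
    per frequency band, data-driven percentile thresholding of
    condition-minus-baseline connectivity matrices, region-of-interest
    connectivity metrics anchored in group-level masks, and linear
    mixed-effects moderation models of connectivity by attachment anxiety
    and avoidance, with Benjamini-Hochberg false-discovery-rate control.
    Includes a synthetic cohort generator with known phase-coupling ground
    truth (band-limited coupled oscillators with circular phase jitter,
    1/f background noise, instantaneous linear mixing as a volume-conduction
    surrogate), EDF+ cohort serialization, behavioural non-parametric
    statistics (Friedman, Dunn, Cohen's d), a repeated-measures ANOVA power
    calculator, and a configuration-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'montage.R'
    'bands.R'
    'synthgen.R'
    'edf.R'
    'spectral.R'
    'connectivity.R'
    'groupmask.R'
    'stats-models.R'
    'power.R'
    'pipeline.R'
    'utils.R'
    'phaseConn-package.R'
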