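Package: cdaction
Title: Correlated Drug Action Models for Drug Combinations in Time and Dose Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits correlated drug action (CDA) models for two-drug
    combinations. The temporal model (tCDA) predicts a combination's
    progression-free survival curve from the two monotherapy survival
    curves and a single Spearman correlation between latent per-patient
    survival times; the dose-space model (dCDA) predicts combination
    viability of cell cultures from monotherapy Hill dose-response curves
    and a Spearman correlation between latent per-cell lethal doses.
    Provides grid-search fitting, bootstrap confidence intervals,
    goodness-of-fit tests, excess-over-CDA and excess-over-Bliss synergy
    metrics, outlier-robust refitting, local per-dose synergy flags,
    rank-correlation-constrained joint simulators (coin and window-swap
    pairing), and synthetic-data generators with known ground-truth
    correlation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
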