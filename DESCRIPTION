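Package: evokedmua
Title: Evoked Multi-Unit Activity Analysis for Cortical Stimulation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for peripheral- and microstimulation-evoked
    cortical spiking recorded on multielectrode arrays. Detects multi-unit
    spikes with a smoothed nonlinear energy operator after elliptic bandpass
    filtering and common average referencing, handles stimulation artifacts
    and blanking, builds square-root-transformed peri-event time histograms
    with Kaiser-weighted Savitzky-Golay smoothing and baseline significance
    thresholds, decomposes evoked responses with a PCA-seeded
    reconstruction-ICA model, and compares component weights across cortical
    area, lesion volume and trial type with mixed-effects models. Includes a
    ground-truthed synthetic cohort generator (inhomogeneous Poisson
    multi-unit activity, stimulation artifacts, configurable effect sizes)
    so the whole pipeline is testable without animal recordings, plus a
    Cavalieri lesion-volume utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    lme4,
    lmerTest,
    MASS,
    nlme,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
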