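Package: neophys
Title: Event and Excitability Analysis for Neonatal Hippocampal Recordings
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification pipelines for developing-hippocampus
    electrophysiology and imaging. Computes dF/F0 with Savitzky-Golay
    baseline oversmoothing, detects somatic calcium transients and
    network events (giant depolarizing potentials) from population
    rasters; extracts intrinsic-excitability features (resting membrane
    potential, membrane resistance, action-potential threshold, rheobase,
    firing rates) from current-clamp sweeps; quantifies miniature and
    evoked EPSCs with failure-mean amplitude correction; and analyses in
    vivo local field potentials (noise-normalized Welch bandpower,
    multitaper spectrograms, early-sharp-wave detection, adaptive
    moving-median/MAD burst detection). A synthetic-data generator with
    machine-readable planted ground truth covers all four modalities so
    every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
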