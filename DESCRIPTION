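Package: regimescope
Title: Classification of Fluctuation- Versus Mean-Driven Neuronal Spiking Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for classifying spinal-neuron spiking into
    fluctuation-driven and mean-driven regimes and quantifying how much of a
    population occupies each regime. Implements the return-map ratio for
    subthreshold membrane-potential trajectories, CV2-based spike-train
    irregularity with TIF50/SIF50 occupancy statistics, phase-plane spike
    threshold estimation, empirical firing-rate-versus-voltage (FV) curves
    with exponential and power-law fits, lognormal firing-rate and Gini
    participation statistics, kernel firing-rate estimation with
    cross-validated bandwidth selection, and inverse-square trilateration of
    extracellular sources on silicon probes. A synthetic-data module
    generates ground-truth-labelled membrane-potential traces, population
    rasters and probe amplitude maps with the statistical structure these
    analyses assume, so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
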