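Package: halospt
Title: Single-Particle Tracking Mobility Statistics and UV-Damage
    Survival Analysis for Archaeal Live-Cell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule live-cell imaging
    experiments in halophilic archaea. Links super-resolution
    localization tables into trajectories, computes jump-distance and
    weighted mean-jump-distance (wMJD) statistics, and compares
    mobility between experimental conditions with a subsampled,
    sample-size-normalized Mann-Whitney U procedure including a
    truncation-aware Gaussian summary. Also fits the Poisson
    zero-event exponential survival model for UV-induced cyclobutane
    pyrimidine dimer damage, and provides supporting ensemble
    analyses: plate-reader growth and fluorescence-per-OD kinetics,
    label-mask cell-shape descriptors, Langmuir monolayer
    compressibility, phosphate standard curves, FTIR preprocessing,
    and precision-weighted localization density rendering. A
    synthetic-data module generates every input format with the
    statistical structure the analyses assume, so the full pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    minpack.lm,
    signal,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
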