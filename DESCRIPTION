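Package: piezotension
Title: Membrane-Tension Sensitivity Analysis for Mechanosensitive Channel
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for combined pressure-clamp electrophysiology
    and DIC imaging of membrane domes in patch pipettes. Estimates dome
    radius of curvature by sub-pixel Gaussian band localisation and weighted
    circle fitting, converts suction and radius to membrane tension via
    Laplace's law, fits Boltzmann pressure- and tension-response curves
    (T50, slope k) per patch and as binned cohort averages, derives
    tension-tuning curves and gating thermodynamics (Gibbs free energy,
    in-plane area expansion), measures single-channel conductance from
    double-Gaussian amplitude histograms and linear I-V fits, fits
    single-exponential inactivation kinetics, and determines whole-cell
    indentation thresholds. Includes a synthetic-data module that renders
    dome micrographs and simulates current sweeps with known ground truth
    so every stage can be validated by parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
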