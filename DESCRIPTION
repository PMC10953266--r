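Package: sgmeg
Title: Spectral Graph Model Analysis of Regional MEG Power Spectra
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward modeling and biophysical parameter inference for a
    linear spectral graph model (SGM) of regional magnetoencephalography
    power spectra. The model couples local excitatory-inhibitory neural
    mass dynamics with long-range transmission over a structural
    connectome through a frequency-dependent complex graph Laplacian,
    yielding a closed-form regional frequency response. The package
    provides the forward model and its stability criterion, per-subject
    parameter estimation by bounded simulated annealing with staged
    stability bounds, empirical spectral features (Welch spectra,
    intrinsic autocorrelation timescales, aperiodic/periodic spectral
    parameterization), cohort-level age-adjusted statistics, random
    forest classification with repeated nested stratified
    cross-validation, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
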