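Package: odnptraj
Title: Trajectory Analysis for Scalar Overhauser Dynamic Nuclear Polarization
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dissects the molecular-dynamics origin of scalar Overhauser dynamic
    nuclear polarization (ODNP) in radical-substrate complexes from femtosecond
    time series of atomic spin densities and geometric observables. Computes
    normalized autocorrelation functions and inter-channel covariances, extracts
    memory kernels by numerically solving the Volterra integral equation of the
    second kind (with an arbitrary-precision contract and a forward-reconstruction
    cross-check), transforms autocorrelation functions to spectral densities
    evaluated at the electron-carbon-13 zero-quantum frequency, inverts
    autocorrelation decays into correlation-time spectra by regularized inverse
    Laplace transformation, fits autoregressive models with information-criterion
    order selection, and computes ODNP bookkeeping quantities (enhancement factors
    with propagated errors, molar-free paramagnetic shifts from titrations,
    complex lifetimes, resonator sample volumes). A synthetic-data module
    generates surrogate trajectories (Ornstein-Uhlenbeck, telegraph pulse-model,
    autoregressive, damped-oscillation) with the statistical structure the
    analysis assumes, so the full pipeline is testable without a quantum
    mechanics/molecular mechanics trajectory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: python3 (only for the precision_digits arbitrary-precision
    paths; double-precision paths are pure R/C++)
Config/testthat/edition: 3
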