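Package: qifbalance
Title: Balanced Excitatory-Inhibitory Networks of Quadratic Integrate-and-Fire
    Neurons and Their Exact Neural Mass Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of sparse balanced excitatory-inhibitory
    networks of quadratic integrate-and-fire neurons with Lorentzian-distributed
    in-degrees, together with the corresponding exact four-dimensional neural mass
    (mean-field) model. Provides stationary balanced-state solutions with
    finite-in-degree expansions, effective input currents and Poissonian
    current-fluctuation amplitudes, Jacobian eigenvalue and Benettin Lyapunov
    spectra, Hopf-bifurcation location by eigenvalue bisection, peak-map
    bifurcation diagrams and dynamical-regime classification, an Euler
    integrator for the spiking network with delta-pulse coupling, and
    macroscopic/microscopic diagnostics (coherence, inter-spike-interval
    variability, power spectra with fundamental-frequency and locking
    detection, rate distributions, excitatory-inhibitory burst delays).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
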