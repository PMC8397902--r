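Package: obvar
Title: Stochastic Firing-Rate Modeling of Olfactory Bulb Spiking Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying odor-evoked changes in spiking variability in the
    mammalian olfactory bulb. Implements a seven-cell stochastic firing-rate model of
    the mitral/periglomerular/granule cell circuit driven by correlated olfactory
    receptor neuron input noise, simulated by Euler-Maruyama over ensembles with
    windowed spike-count statistics; a self-consistent steady-state approximation of
    the first- and second-order statistics via Gauss-Hermite quadrature; Halton-sequence
    screening of the inhibitory and excitatory coupling space against target statistics
    with weighted error functionals; a trial-structured experimental spike-statistics
    pipeline (PSTH, spike-count variance and covariance, Fano and correlation slopes,
    mean matching, Welch tests); and doubly stochastic synthetic spike-train and
    target generators with known ground truth for recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
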