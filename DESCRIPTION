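Package: habinfo
Title: Information Thermodynamics of a Minimal Habituation Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solver and exact stochastic simulator for a minimal
    receptor-readout-storage model of habituation to repeated stimuli.
    Implements the timescale-separation solution of the chemical master
    equation (conditional stationary laws, spectral storage propagator,
    Chapman-Kolmogorov iteration), an exact Gillespie oracle, the five
    classical habituation hallmarks (potentiation, spontaneous recovery,
    subliminal accumulation, intensity and frequency sensitivity),
    information-theoretic observables (mutual information between readout
    and signal, feedback information) and stochastic-thermodynamic
    observables (internal energy flux, receptor dissipation), Pareto
    information-dissipation optimization over the inverse temperature and
    storage cost, and a binary-neuron mapping with PCA embeddings for
    comparison with population recordings of neural habituation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
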