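Package: neuralwave
Title: Neural Wave Interference in Distributed Excitatory-Inhibitory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a cortical circuit as a spatially distributed chain (or
    two-dimensional lattice) of Wilson-Cowan excitatory-inhibitory motifs whose
    responses to localized input are spatially damped standing waves.  Provides
    numerical integration of the discrete chain and its continuum
    reaction-diffusion limit, the analytic Green's function of the linearized
    circuit, superposition and interference analysis for patterned stimuli,
    linear spatiotemporal resonance analysis (wave-component interaction
    matrix, determinant decomposition, spatial and temporal resonance curves
    and their two regimes), a nonlinear harmonic-balance solver for
    contrast-dependent resonance shifts, single-node temporal interference and
    duration thresholds, and the accompanying empirical analysis toolkit:
    sliding-kernel tuning aggregation, bootstrap tuning-peak estimation,
    damped-harmonic fits of lateral sensitivity profiles, and an adaptive
    three-down/one-up staircase simulator, together with seeded synthetic-data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
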