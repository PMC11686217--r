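Package: zenospin
Title: Quantum Zeno Magnetosensitivity of Strongly Coupled Radical Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reactive spin dynamics of radical pairs at contact distance, built
    around asymmetric Haberkorn recombination (the quantum Zeno regime) for a
    triplet-born flavin semiquinone / superoxide pair. Constructs composite-space
    spin operators, Zeeman, hyperfine, electron-electron dipolar (point-dipole and
    distributed spin density) and exchange Hamiltonians, solves singlet
    recombination yields by the Laplace-domain linear system of the reactive
    Liouvillian, and adds Nakajima-Zwanzig relaxation superoperators evaluated in
    the non-Hermitian eigenbasis of the effective Hamiltonian for random-field,
    fluctuating-dipolar and exchange noise channels. Provides directional
    magnetic-field-effect anisotropy maps over Fibonacci-sphere orientations,
    recombination-rate heatmaps, effective-Hamiltonian spectra exhibiting the
    quantum Zeno 1/k_S scaling, and a synthetic generator for displacement
    distributions, dipolar-tensor covariances, spin-density spreads and tilted
    hyperfine tensors standing in for molecular-dynamics-derived inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
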