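Package: extensivity
Title: Entropy Extensivity in Evolving Two-Layer Multiplex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when the sum of positive Lyapunov exponents
    (a Kolmogorov-Sinai entropy proxy, H_KS) of a two-layer multiplex network
    grows linearly with network size. Provides generators for circulant,
    small-world, complete and Erdos-Renyi layers and their supra-Laplacians;
    closed-form Lyapunov spectra and first-order H_KS expansions for
    diffusively coupled shift-map multiplexes; a Hindmarsh-Rose neuronal
    multiplex simulator with full tangent-space (Benettin) Lyapunov-spectrum
    computation in compiled code; a greedy evolutionary algorithm that adds
    inter-layer connections accepted only when they increase H_KS; and
    extensivity classification via linear and log-log scaling fits, together
    with the spectral invariance constants that govern Lyapunov-spectrum
    collapse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
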