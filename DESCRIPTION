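Package: grnevolve
Title: Forward-in-Time Simulation of Gene Regulatory Network Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of a haploid population of
    gene regulatory networks. Each gene carries binary 'cis' and 'trans'
    regulatory regions whose shared set bits determine a signed interaction
    matrix; expression is a boolean vector iterated to a fixed point or cycle
    during a maturation phase, and fitness is a Gaussian-type function of the
    distance between the matured expression profile and an optimum. Includes a
    Poisson bit-flip mutation model, two recombination models (cis-swapping and
    a single-breakpoint crossover), per-generation statistics with distinct
    genotype accounting, and experiment harnesses for mutational robustness
    probing, neutral-gene interaction accounting, and a regulation-free
    baseline model for quantifying mutational buffering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
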