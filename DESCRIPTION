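Package: tesim
Title: Forward Simulation of Transposable Element Dynamics under
    Copy-Number-Dependent Epigenetic Silencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of transposable element (TE)
    copy-number evolution in a diploid population with separate sexes,
    random mating and discrete generations.  Individual fitness follows
    additive, multiplicative or synergistic interactions among TE fitness
    effects, and host epigenetic silencing of TEs is modelled as a
    copy-number-dependent Poisson magnitude that inflates selection against
    silenced copies (spreading of repressive marks) and/or suppresses their
    transposition.  Includes modifier-allele invasion experiments for loci
    that strengthen or weaken silencing, a dominant-lethal ectopic
    recombination model between heterozygous TE pairs with optional
    silencing-mediated suppression, an analytical transposition-selection
    balance solver for equilibrium copy numbers, replicate outcome
    classification, and parameter-sweep orchestration with deterministic
    seed management.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
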