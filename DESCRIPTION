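Package: seapopgen
Title: Population Genetics and Seascape Connectivity for Marine Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterise the population genetic structure and
    dispersal dynamics of marine invaders sampled at multiple localities.
    Implements sequence-based diversity and differentiation statistics
    (haplotype and nucleotide diversity, TN93+Gamma distances, AMOVA-based
    Phi-ST with permutation tests, hierarchical AMOVA, mismatch-distribution
    expansion fits, Tajima's D and Fu's Fs), microsatellite statistics
    (heterozygosities, F-IS, rarefied allelic richness, EM estimation of
    null-allele frequencies, Weir-Cockerham theta with and without the ENA
    null-allele correction, heterozygosity-excess bottleneck tests),
    approximate Bayesian computation for invasion-scenario choice, Lagrangian
    particle tracking on gridded velocity fields reduced to larval
    connectivity matrices, and Mantel tests relating genetic differentiation
    to geographic distance and oceanographic connectivity. A synthetic-data
    module provides coalescent simulators and analytic flow fields so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    nnet,
    stats,
    utils,
    jsonlite
Suggests:
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
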