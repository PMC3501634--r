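Package: msatdemog
Title: Historical Demography from Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coalescent-based inference of historical population demography
    from diploid microsatellite genotypes. Provides GenePop/CSV input with
    locus-level quality control, per-locus diversity statistics with
    permutation tests (Hardy-Weinberg G-test, genotypic disequilibrium,
    Weir-Cockerham F_IS), population-structure screening via R_ST and
    delta-mu-squared neighbor-joining, bottleneck tests (heterozygote excess
    under the two-phase mutation model, allele-frequency mode shift,
    Garza-Williamson M-ratio with a simulation null), a family of twelve
    bounded-lattice continuous-time Markov chain mutation models, a
    coalescent simulator for synthetic genotype data under parametric
    demographies, and multi-locus Bayesian skyline inference of effective
    population size through time with marginal-likelihood model selection
    by Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
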