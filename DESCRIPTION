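Package: beeblup
Title: Honey Bee Breeding Simulation and Single-Step Genomic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of a honey bee (Apis mellifera)
    breeding population with a realistic 16-chromosome genome, polyandrous
    mating via dummy sires, overlapping generations, and colony traits with
    maternal (queen) and direct (worker) genetic effects. Implements genetic
    evaluation with a maternal-effects animal model under two relationship
    kernels: the pedigree numerator relationship matrix adapted to uncertain
    paternity through a paternal path coefficient, and the unified single-step
    matrix H combining pedigree and genomic (VanRaden) information. Provides
    replicate drivers that measure the accuracy of estimated breeding values
    (correlation with true breeding values) for juvenile and all queens across
    heritability and maternal-direct correlation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
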