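Package: mirfate
Title: Birth, Death and Adaptive Evolution of MicroRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evolutionary-genetics pipeline for dating the origin of
    microRNA genes on a species phylogeny, testing for adaptive evolution
    with the McDonald-Kreitman framework (including the proportion of
    adaptive fixations, alpha), scanning loci with site-frequency-spectrum
    statistics (Watterson's theta, pi, Fay and Wu's theta_H), measuring
    population differentiation (Weir-Cockerham Fst for inbred haploid
    lines), scoring conservation with Kimura 2-parameter precursor
    divergence against Nei-Gojobori synonymous divergence (K_miR/K_S),
    classifying each gene's evolutionary fate (adaptive, conservative or
    transitional), and accounting for gene turnover under a constant
    birth-rate birth-death model. Ships synthetic-data generators that
    emulate every input so the full pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
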