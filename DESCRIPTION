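Package: hearQTL
Title: Replication Analysis of Quantitative Hearing Trait Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for candidate-gene replication studies of quantitative
    audiometric traits in population cohorts. Derives hearing endophenotypes
    (single-frequency thresholds, pure-tone averages and threshold principal
    components) from audiograms, adjusts them for sex, age and genomic kinship
    with a GRAMMAR-style two-stage mixed model, tests SNPs under additive,
    dominant, recessive and overdominant codings, runs a gene-based test on
    principal components of intragenic genotypes, filters genome-wide
    association hits down to candidate genes, and profiles genotype-stratified
    audiograms. Includes a synthetic-cohort generator with linkage
    disequilibrium, sibling relatedness and a polygenic trait model so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
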