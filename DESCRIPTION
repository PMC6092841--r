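Package: ycapture
Title: Evaluation of Y-Chromosome Capture Enrichment in Ancient DNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of in-solution Y-chromosome capture-enrichment
    experiments on ancient DNA sequencing libraries. Generates truth-labeled synthetic
    libraries and capture rounds with realistic endogenous fractions, fragment-length
    distributions and finite-pool clonality; accounts reads (coordinate deduplication,
    on/off-target classification, seeded down-sampling replicates, binomial confidence
    intervals); computes fold-enrichment grids between experimental conditions;
    extrapolates library complexity into yield and enrichment curves via a
    zero-truncated negative-binomial model with bootstrap uncertainty and a linear
    fallback for duplicate-free libraries; determines genetic sex from sex-chromosome
    read counts (Ry statistic); and assigns Y haplogroups by haploid genotype sampling
    and a most-derived-SNP tree search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
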