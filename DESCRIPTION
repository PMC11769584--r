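Package: cultivarpopgen
Title: Population Genomics and Genomic Prediction for F1-Dominated Cultivar Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing resequencing panels of F1-hybrid crop
    cultivars released over decades of breeding: chromosome-length-weighted
    additive and dominance genomic relationship matrices with
    principal-component structure analysis, GBLUP genomic prediction
    (REML and Gibbs paths) with replicated cross-validation, mixed-model
    genome-wide association scans with exact likelihood-ratio tests,
    windowed nucleotide diversity and reduction-of-diversity sweep scans,
    a heterozygosity-excess statistic tailored to hybrid panels,
    linkage-disequilibrium decay curves from genotypes or phased
    haplotypes, and a forward-in-time breeding-program simulator used for
    validation and benchmarking of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    vcfR,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
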