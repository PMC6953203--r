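Package: anthomap
Title: Bulked Segregant Mapping of Epistatic Anthocyanin Loci in Lettuce
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for dissecting the four-locus
    epistatic genetic architecture of red leaf colour in lettuce. Provides a
    genotype-to-colour trait model (a recessive-null bHLH locus epistatic over
    a dominant MYB activator and two recessive intensifiers), a pedigree
    simulator for biparental crosses (F1, F2, selfed F2:3/F4 families) with
    Haldane recombination on a nine-chromosome map, pooled-read sampling for
    bulked segregant analysis (BSA), the delta SNP-index scan statistic with
    Monte-Carlo null confidence bands and candidate-region calling, Mendelian
    segregation and marker-association chi-square tests, epistasis-aware
    fixed-background family selection, recessive-class fine mapping, and
    annotation of candidate-gene variants (frameshift, missense, promoter
    indels) against simple gene models.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    yaml,
    generics,
    withr,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
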