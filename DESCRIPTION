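Package: somaticpair
Title: Somatic Alteration Detection in Matched Tumor/Normal Whole-Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detectors for somatic alterations in matched tumor/normal
    whole-genome sequencing: a per-strand pileup genotype caller based on a
    Kolmogorov-Smirnov-like distance between observed and expected diploid
    base distributions with somatic subtraction against the matched normal;
    a sliding-window copy-number scanner on insert-gated physical coverage
    with tumor/normal log2 ratios; a two-step somatic indel filter using an
    insert-size gate and a flanked normal-region test; and a discordant
    read-pair interchromosomal translocation detector with a mean plus
    3-standard-deviation outlier cutoff. A synthetic tumor/normal read-pair
    simulator with a fully known truth set makes the whole pipeline
    exercisable and verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
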