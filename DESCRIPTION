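Package: aacons
Title: Conservativeness of Amino Acid Substitutions Across Protein
    Evolutionary Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Asks whether the amino-acid changes observed in slowly evolving
    proteins - fixed differences between orthologs and standing missense
    variation - are enriched in conservative (biochemically similar)
    replacements relative to fast evolving proteins. Provides four 20x20
    conservativeness scoring matrices with strict per-matrix cutoffs
    (BLOSUM62, an exchangeability-style matrix, and side-chain volume and
    polarity delta matrices), pairwise ortholog alignment with BLAST-style
    statistics, evolutionary-rate classification by percent identity,
    pooled conservative-fraction tables, minor-allele-frequency stratified
    missense variant analysis, chi-squared group comparisons, an
    overlap-ratio diagnostic of mutation saturation, and a Poisson
    substitution-process simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
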