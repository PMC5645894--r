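Package: atlaskit
Title: Comparative Statistics for Multi-Library RNA-Seq Expression Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for tissue/stage expression atlases built from many
    RNA-seq libraries: per-gene z-score standardization of FPKM values and
    calling of library-correlated genes, pairwise library similarity via an
    exact hypergeometric overlap tail probability with Bonferroni correction
    and -log10 "mapping scores", per-base coverage analytics (transcribed
    genome fraction, BPKM normalization, geometric rank strata), read- and
    gene-composition classification (mitochondrial/rRNA/coding/noncoding,
    keyword-based hit triage), and genome- or FPKM-weighted transcriptome
    codon-usage profiling with tRNA gene-count correlation. Includes seeded
    synthetic-atlas generators that plant known tissue markers, heavy-tailed
    depth tracks, toy transcriptomes and hit tables so every stage can be
    exercised against a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite,
    withr
Config/testthat/edition: 3
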