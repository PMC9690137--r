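Package: codonbias
Title: Codon Usage Bias Indices and Expression Prediction for Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads, validates and deduplicates coding sequences from FASTA,
    counts codons, and computes the classical codon usage bias indices: the
    codon adaptation index (CAI), relative synonymous codon usage (RSCU, in
    both the within-family-fraction and the classical conventions), relative
    codon bias strength (RCBS) and its family-normalised modification
    (MRCBS).  Downstream summaries include fixed-effects sequential-SS
    ANOVA of index tables, a per-codon z-screen, an empirical normality
    summary, and correlation-matrix PCA across indices.  A synthetic
    coding-sequence generator with known codon-preference ground truth makes
    the whole pipeline testable without downloads.  All user-facing
    functions take data frames first and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
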