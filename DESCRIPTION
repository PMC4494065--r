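Package: oxphosseq
Title: Targeted OXPHOS Panel RNA-Seq: Quantification, Compartment
    Normalization, Differential Expression and Pooled Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for targeted RNA-seq of the oxidative
    phosphorylation (OXPHOS) gene panel in thermally stressed redband
    trout and similar pooled factorial designs. Provides a validated
    gene-panel container with codon-effect annotation under the standard
    and vertebrate mitochondrial genetic codes, a synthetic-data
    generator for the 3 strain x 2 temperature x 3 tank x 4 timepoint
    pooled design with planted expression effects, variants and A-to-G
    editing sites, an alignment-free unique k-mer quantifier with
    per-site pileups, per-genome-compartment proportional expression
    indices, per-gene two-way ANOVA with Welch post-hoc contrasts and
    Benjamini-Yekutieli false-discovery-rate control with signed fold
    changes, and a pooled-sample variant and RNA-editing caller based on
    binomial confidence-interval scores with chi-square and F-test
    population comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
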