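Package: truncscore
Title: Sequence-Based Pathogenicity Scoring of Protein-Truncating Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation and pathogenicity scoring of protein-truncating
    variants (stop-gains and frameshifts) on transcript models. Computes
    per-variant sequence features across all isoforms of a gene (fraction of
    protein truncated, domain truncation, isoform usage, principal-isoform
    damage, and predicted nonsense-mediated decay via the 50-nucleotide rule),
    combines them in a naive Bayes posterior probability of pathogenicity,
    and provides the surrounding evaluation machinery: repeated-subsampling
    ROC curves, column-shuffle randomization tests, joint scores with
    gene-level constraint metrics, rank percentiles, exact Hardy-Weinberg
    filtering, allele-frequency trend regression, and carrier expression
    z-scores. A seeded fixture generator emulates every input so the full
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
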