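Package: viromecore
Title: Annotation-Confidence Analysis for Mosquito Virome Metagenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the confidence of taxonomic annotations in
    viral metagenomes assembled from mosquito pools. Ingests BLAST-style
    tabular hit tables, filters and clusters hits by NCBI taxonomy identifier,
    assigns taxa by best hit or lowest common ancestor, normalizes abundance
    as RPKM, and separates a high-confidence "core virome" from largely novel
    sequences with a two-dimensional goodness-of-assignment classification
    (percent query coverage by percent pairwise identity). Includes a
    mutation-simulation calibration of annotation drift, cross-pool richness
    and ecosystem-signature summaries, circular (CRESS-DNA-like) genome
    analyses (terminal-repeat circularity detection, species demarcation,
    in-silico PCR), and a ground-truthed synthetic virome generator so the
    whole workflow runs without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
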