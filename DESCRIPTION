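Package: mobkit
Title: Plasmid Reconstruction, Clustering and Mobility Typing from Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising bacterial plasmids from draft or complete
    genome assemblies. Builds reference plasmid databases with stable nested
    cluster codes from MinHash genomic distances and single-linkage clustering;
    reconstructs plasmid units from assembly contigs by marker detection and
    winner-take-all reference bit-score aggregation; types plasmids by replicon
    and relaxase (MOB) families and predicts conjugative transferability from
    relaxase, mate-pair-formation and oriT evidence. Includes a deterministic
    synthetic-data generator (reference sets, genomes, fragmented assemblies
    with ground truth) and benchmarking utilities for base-level
    sensitivity/specificity and per-plasmid reconstruction event taxonomy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
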