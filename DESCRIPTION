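Package: crisprmob
Title: CRISPR-Cas Detection, Curation and Targeting Analysis for Plasmid Communities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects CRISPR arrays on plasmid and chromosome sequences,
    removes false-positive tandem repeats with a quarantine/rescue
    curation algorithm (repeat conservation, spacer conservation, spacer
    length standard error, ORF overlap; cas-proximity and trusted-repeat
    rescue; trusted-repeat secondary search), assembles CRISPR-Cas loci
    by distance linkage and repeat-similarity association, and computes
    mobilome defence statistics: per-replicon and per-Mbp prevalence,
    binary indicator-value (IndVal) enrichment with permutation p-values,
    Fisher 2x2 enrichment, spacer-protospacer matching with
    Karlin-Altschul expectation values, conjugative targeting weights,
    and taxonomic confinement of the plasmid-plasmid targeting network
    with a label-permutation null. Includes a synthetic plasmid-community
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    igraph,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
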