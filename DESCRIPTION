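Package: maveintegrate
Title: Integrate Multiplexed Variant Abundance and Activity Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring FACS sort-seq (VAMP-seq style) deep mutational
    scanning experiments and integrating the resulting steady-state abundance
    scores with orthogonal enzymatic activity measurements. Provides
    bin-weighted abundance scoring with synonymous/nonsense anchoring, a
    bootstrapped replicate-count filter, composite score aggregation with
    confidence classes, a four-way abundance-by-activity functional
    classification, a codon-degeneracy single-nucleotide-variant null spectrum,
    class enrichment analysis against clinical and somatic variant catalogs,
    per-position mutational tolerance profiling with hierarchical clustering,
    and a fully synthetic sort-seq data generator so the entire pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
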