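Package: repclone
Title: Clonal Overlap Analysis of T Cell Receptor Repertoires Across Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of T cell receptor beta-chain CDR3 repertoires from
    paired tissue samples (human lung and lung-draining lymph node T cell
    subsets). Reads MiXCR- and AIRR-style clone tables, enforces the
    productive-rearrangement filter, collapses reads into clonotypes by CDR3
    nucleotide identity, and quantifies clonal structure: per-sample
    clonality and analytic rarefaction, sample-by-clonotype overlap matrices
    under sharing filters, per-donor hierarchical clustering with an exact
    binomial test of tissue concordance, pooled classical multidimensional
    scaling with distance-group comparisons, and frequency-independent V-J
    gene-segment usage bias. A seeded synthetic repertoire generator with a
    configurable three-way sharing structure, power-law clone sizes and V-J
    usage bias makes the whole pipeline runnable and testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
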