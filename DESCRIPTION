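Package: plastomics
Title: Comparative Plastome Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Site-level SNP and indel classification of whole-plastome
    multiple alignments, private/shared SNP partitioning across species
    subsets, sliding-window variability profiling with hotspot and
    high-deletion-region detection, windowed percent-identity profiles,
    p-distances under complete deletion, Tajima's one-degree-of-freedom
    relative rate test, and quadripartite plastome structure summaries
    (inverted-repeat detection, LSC/SSC partition, GC content, gene census).
    Includes a synthetic plastome-alignment generator with full ground truth
    for validation, and an end-to-end pipeline writing standard TSV/BED/JSON
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
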