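Package: apamaps
Title: Polyadenylation-Site Cluster Calling, APA Change Detection, and
    Positional Binding Maps from Targeted 3' End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls polyadenylation-site (PAS) clusters from strand-specific
    3' end read coverage, removes internal-priming artifacts with A-run and
    A-content heuristics plus hexamer and reference-database filters,
    quantifies relative PAS usage within terminal exons, and calls
    alternative-polyadenylation (APA) changes between knockdown and control
    replicates. Builds positional RNA maps of RNA-binding-protein (RBP) peak
    occupancy around regulated PAS with bootstrap bands and per-position
    Fisher tests, sliding-window motif and G/C frequency maps, UGUA-to-hexamer
    spacing distributions, and DMS-accessibility comparisons of cis-elements.
    A synthetic-data generator with planted ground truth emulates all external
    inputs so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
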