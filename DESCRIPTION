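Package: uroscape
Title: Downstream Somatic-Genome Analysis of Bladder Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable downstream analysis of somatic whole-genome calls from
    urothelial (bladder) carcinoma cohorts: six-class substitution spectrum
    profiling and comparison, a SIFT/PolyPhen2/truncation/recurrence driver
    prioritization cascade, 1-Mb windowed mutation hotspot scanning,
    copy-number burden and chromothripsis calling, amplicon allele-fraction
    profiling, copy-number- and purity-adjusted clonal clustering via a
    Dirichlet-process binomial mixture, and rank-based statistics linking
    mutation burden to stage and grade. Includes a synthetic tumour/normal
    cohort generator so every stage is testable without access-controlled
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    graphics,
    vcfR,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
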