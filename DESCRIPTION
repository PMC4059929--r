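Package: gfinet
Title: Copy-Number Variant Association and Gene-Family Interaction Network
    Enrichment for Case/Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case/control copy-number variant (CNV) analysis:
    sample-level quality control with identity-by-state duplicate removal and
    supervised nearest-centroid ancestry classification; construction of
    copy-number variable regions (CNVRs) from call boundaries with one-sided
    Fisher's exact association, discovery-replication filtering and
    permutation-based genome-wide burden testing; and gene-family interaction
    network (GFIN) enrichment, in which the directed interaction network
    spawned by a gene family's members is scored for cumulative CNV enrichment
    in cases and calibrated against networks grown from random seed sets of the
    same size. A synthetic-cohort generator with planted effects makes every
    stage testable without access to genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
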