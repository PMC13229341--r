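Package: markerdetect
Title: Species Detection from Marker-Gene Phylogenetic Placements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects which species are present in a metagenomic sample by
    aggregating per-read maximum-likelihood phylogenetic placement supports
    across single-copy marker genes. Reads jplace v3 placement files against
    rank-annotated reference taxonomies, converts per-edge supports into
    clade supports and per-rank read classifications, and scores each
    species by marker vote (fraction of marker genes with at least one read
    whose best-supported species is s) or marker confidence (mean over
    marker genes of the average non-zero placement support for s). Species
    are called present when the score reaches a threshold, and the package
    computes precision/recall/F1, threshold-sweep precision-recall curves
    with AUPR, precision at fixed recall for low-abundance species, and
    false-positive reports. A seeded placement-level community simulator
    makes the whole pipeline testable without external placement tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
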