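Package: depclad
Title: Dependency-Aware Morphological Parsimony with Composite Characters
    and Implied Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for cladistic analysis of morphological character
    matrices with ontological character dependencies. Reads and writes
    TNT-dialect (xread) and NEXUS matrices, parses hierarchical
    dependency annotations (controller states gating the applicability
    of dependent characters) and serial-homologue blocks, rewrites each
    dependency complex into a composite character with an explicit
    tuple-state space and a generated step (cost) matrix so that
    inapplicable cells never contribute phantom transformation steps,
    and scores trees by Fitch and generalized (Sankoff) parsimony under
    equal or implied weighting, including a k-value sweep and an
    automatically derived concavity constant from a maximum weight
    ratio. Includes heuristic tree search (random addition, NNI/SPR/TBR
    swapping, ratchet and drift perturbation) with a deduplicated tree
    collection and closure protocol, bootstrap resampling, strict
    consensus, normalized Robinson-Foulds distance matrices with SVG
    heat maps, congruence-based selection of most parsimonious trees,
    and a synthetic-data generator producing matrices with known true
    trees, dependency complexes, serial blocks and missing data for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
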