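Package: phagescan
Title: Phage-Display Deep-Sequencing Epitope Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for antibody epitope mapping with
    gene-fragment phage-display libraries read out by deep sequencing.
    Classifies library inserts by cloning orientation and reading frame
    (the 1/18 natural-frame lottery), builds per-residue occurrence and
    pseudocount-stabilised enrichment-factor profiles from unselected
    versus affinity-selected libraries, flags significantly enriched
    fragments by a mean plus five standard deviations rule, localises
    epitope hot-spot boundaries as abrupt enrichment-factor jumps, and
    estimates solution-phase dissociation constants from
    competition-ELISA data by the Friguet linearisation.  A biopanning
    simulator with known ground truth makes every stage testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
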