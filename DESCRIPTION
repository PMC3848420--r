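Package: lrrscan
Title: Leucine-Rich Repeat Architecture Annotation and Coarse Solenoid Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus-pattern detection of ribonuclease-inhibitor-like
    leucine-rich repeats (LRRs) in protein sequences, with two alternating
    repeat types, dynamic-programming segmentation into tandem repeat runs,
    exon-phase mapping of repeats onto consensus coordinates, scanning for
    NACHT-domain functional motifs (Walker A/B, Sensor 1, AxP, winged-helix
    consensus), nuclear localization signal basic clusters and
    cysteine-spacing capping motifs, and a coarse-grained C-alpha solenoid
    geometry builder with PDB output. Includes a fully seeded synthetic
    protein and exon-table generator with planted ground truth so the whole
    pipeline is testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
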