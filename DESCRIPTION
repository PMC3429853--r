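Package: mirscan
Title: Design and Scoring of Efficient miR30-Based shRNA Guide Strands
Version: 1.0.0
Authors@R:
    person("mirscan", "maintainers", email = "mirscan@example.org",
           role = c("aut", "cre"))
Description: Thermodynamic and position-dependent sequence scoring of 22-nt
    shRNA guide strands in the miR30 backbone. Implements nearest-neighbor
    RNA-RNA duplex free energies, a minimum-free-energy folder for short
    oligonucleotides, inter-molecular dimer energies, a published
    multiple-regression silencing-efficiency model, artifact filters (motifs,
    low complexity, guide self-structure, miRNA seed matches), a transcript
    scanner with ranked output, and the full training pipeline (correlation
    screening with split-stability, OLS with iterative term reduction,
    non-overlapping cross-validation, ROC) so the model can be refit on any
    guide/activity table. A seeded synthetic-data generator makes every
    pipeline stage testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
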