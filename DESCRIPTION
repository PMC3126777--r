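Package: paraloop
Title: Paralog-Divergent Surface-Loop Discovery and Comparative Protein Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for locating candidate kinase-independent functional sites on
    a protein paralog: progressive multiple alignment and paralog-contrast
    conservation scanning, comparative (homology) model construction with
    torsion-space and Cartesian minimisation, random-tweak loop closure and
    rotamer-library side-chain placement, DSSP-like secondary-structure
    assignment, Shrake-Rupley accessible surface area, Kabsch superposition,
    statistical-potential model assessment, and surface-loop candidate-site
    nomination. Also includes regression screens for protein co-expression
    panels, compound-response table analyses with dose and structure-activity
    logic, and deterministic synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
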