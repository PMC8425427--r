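Package: c2contact
Title: Inter-Chain Residue Contact Prediction for C2-Symmetric Homodimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts inter-protein residue-residue contacts across the
    interface of C2-symmetric homodimers from a monomer structure and a
    multiple sequence alignment. Implements the full feature pipeline
    (minimal heavy-atom distance maps, secondary structure, solvent
    accessible surface area, Wimley-White hydrophobicity, sequence
    profiles, mean-field direct-coupling analysis with average product
    correction, and an FFT shape-complementarity docking map), a deep
    residual contact network trained with focal loss under C2
    symmetrization, direct-coupling baselines with an intra-monomer
    distance filter, the standard contact-prediction evaluation
    statistics, a contact-guided post-docking pose filter, and a
    synthetic fixture generator so that every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    seqinr,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
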