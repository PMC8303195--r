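Package: irising
Title: Seeded Ising Model Toolkit for Distributed Biometric Template
    Storage and Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the security of distributed storage and
    matching of binary biometric phase-code templates (iris codes and
    similar 2-D binary lattices with occlusion masks).  Implements the
    masked fractional Hamming distance and an occlusion-penalising
    modified Hamming distance; division of templates into partial
    templates by block-form, R-dispersion or Z-dispersion; a silo-based
    distributed matching protocol that aggregates per-silo partial
    scores over rotation shifts; reconstruction of "intruder templates"
    from leaked partial templates by Metropolis sampling of a Seeded
    Ising Model (an Ising model with frozen seed bits), including
    snapshot majority voting and bagging over complementary partial
    templates; and an evaluation harness computing match-rate curves,
    FMR/FNMR/EER and Intruder Match Rates on synthetic template
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
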