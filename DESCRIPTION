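Package: smbjr
Title: Single-Molecule Break-Junction Conductance Analysis for DNA
    Conformation Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule break-junction (SMBJ)
    conductance-distance retraction traces for mixtures of B-form duplex DNA
    and G-quadruplex junctions.  Provides a seeded synthetic trace generator
    (exponential tunneling decays, species-specific conductance plateaus,
    instrument noise floor), the two-criterion automated trace screen
    (semi-log line-fit residual plus per-trace histogram spike), composite
    semi-logarithmic conductance histograms with Gaussian peak fitting in
    log-conductance, conformation assignment against reference conductances,
    a potassium-chloride environment switch that suppresses antiparallel
    G-quadruplex junction formation, and concentration-ratio titration of
    two-conformation mixtures read out as the peak-height ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
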