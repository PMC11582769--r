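Package: estrocycle
Title: Coupled Estrogen-Receptor Signalling and Cell-Cycle Dynamics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Ordinary differential equation models of 17beta-estradiol (E2)
    induced ERalpha target-protein dynamics (GREB1, PR, TFF1) in MCF7 cells,
    coupled one-way to a CDK1/APC relaxation oscillator for in-silico cell
    cycle phase calling, with an experimental-protocol and gene-knockdown
    simulator, multi-start least-squares calibration under steady-state
    constraints, a FUCCI single-cell track processing pipeline with phase
    assignment and duration statistics, nucleus distance-map construction and
    watershed reconstruction, and seeded synthetic-data generators for every
    input class.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
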