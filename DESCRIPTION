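Package: refkin
Title: Reference-Tissue Kinetic Quantification for Dual-Tracer Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification tools for reference-tissue
    analysis of dynamic brain PET. Implements the simplified reference
    tissue model (SRTM, basis-function solution), reference Logan
    graphical analysis and standardized uptake value ratios (SUVR),
    regionally and voxelwise; time-stability sweeps of scan duration,
    Logan t* and static acquisition windows; dynamic-versus-static
    agreement regression; and signed-R2 cross-tracer regional
    correlation matrices. A synthetic-data module generates
    multi-subject dual-tracer cohorts of regional time-activity curves
    and labelled 4D phantoms with known ground-truth kinetics,
    frame-count-based noise and a Gaussian-copula correlation structure
    between regional binding potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    ggplot2,
    pracma,
    rlang,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
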