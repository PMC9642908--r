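Package: odaciti
Title: Periarteriolar Oxygen Gradient Analysis and CMRO2 Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the cerebral metabolic rate of oxygen (CMRO2) from
    periarteriolar tissue pO2 maps acquired by two-photon phosphorescence
    lifetime microscopy. Implements the ODACITI diffusion model (oxygen
    delivery from arterioles and capillaries into tissue) together with the
    classical Krogh-Erlang cylinder solution, phosphorescence decay fitting
    and lifetime-to-pO2 calibration, radial region-of-interest segmentation
    of measurement grids, a finite-difference Poisson forward simulator for
    synthetic microvascular oxygen fields, and laminar (cortical-depth)
    summary statistics. All validation experiments are regenerated from
    synthetic data; no external dataset is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
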