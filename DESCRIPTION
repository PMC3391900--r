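Package: ribodosim
Title: Fluorescence Dosimetry of Riboflavin Diffusion in the Cornea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for corneal cross-linking fluorescence dosimetry.
    Simulates cross-sectional slit-fluorescence images of riboflavin diffusing
    into the cornea, extracts depth-calibrated intensity profiles (baseline
    subtraction, surface detection, cosine correction for oblique viewing),
    and estimates diffusion coefficients by nonlinear least squares against
    the semi-infinite solution of Fick's second law, both single-layer and
    biphasic (epithelium/stroma). Also computes membrane diffusivity from
    Franz-cell cumulative-permeation series via Fick's first law, and tracks
    UVA dose and riboflavin photo-consumption during irradiation. Includes an
    explicit finite-difference oracle for the diffusion equation and a fully
    seedable synthetic-data generator so every stage is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
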