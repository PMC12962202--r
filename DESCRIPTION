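Package: famfat
Title: Flip-Angle-Modulated Chemical-Shift-Encoded MRI for Proton-Density
    Fat-Fraction Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for flip-angle-modulated (FAM) 2D
    chemical-shift-encoded MRI. Designs centric-ordered variable-flip-angle
    spoiled-gradient-echo protocols (flip schedules, k-space weighting,
    point-spread-function metrics, Cramer-Rao echo-time evaluation), forward
    simulates multi-echo acquisitions of a digital PDFF-T1 vial phantom under
    transient or steady-state regimes, estimates proton-density fat fraction
    (PDFF), R2* and B0 field maps by confounder-corrected magnitude, complex
    and hybrid fitting, and computes the bias, noise and Bland-Altman
    agreement statistics used to validate quantitative fat-water imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
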