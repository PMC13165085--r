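Package: vinestress
Title: Early Water-Stress Detection in Grapevine from Proximal Hyperspectral Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting the onset of water stress in individual
    grapevines from proximal VIS-NIR (400-1000 nm) hyperspectral image time
    series. Implements ENVI-style cube input/output with dark/white
    reflectance calibration, leaf-pixel sampling, chemometric preprocessing
    (Standard Normal Variate, Savitzky-Golay smoothing, mean centering),
    per-plant principal component score spaces with a day-one baseline, a
    Mahalanobis divergence statistic with rank-test change-day assignment,
    PC1-loading wavelength-importance extraction, and the stem-water-potential
    reference analysis (Lilliefors normality screening, log transform,
    per-day one-way ANOVA and Duncan's multiple range test). A seeded
    synthetic-scene generator emulates vegetation reflectance with pigment
    and water absorption features, a red edge, illumination drift and
    heteroscedastic sensor noise, providing ground-truth stress-onset days
    for validation.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
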