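Package: lensepr
Title: Spin-Label EPR Analysis of Alpha-Crystallin Binding to Lens-Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying alpha-crystallin association with
    cholesterol-containing model human lens-lipid membranes from
    continuous-wave EPR spectra of the cholestane spin label. Provides a
    synthetic first-derivative spectrum generator with known ground truth,
    extraction of peak-to-peak line features (mobility parameter h+/h0,
    maximum splitting, rigid-limit 2Az hydrophobicity), conversion of
    low-field amplitude loss into the percentage of membrane surface
    occupied with a spherical-vesicle outer-leaflet correction, one-site
    ligand-binding fits (MMSO and Ka), membrane-composition calculus
    (cholesterol mixing ratio, mol%, cholesterol-bilayer-domain onset), and
    replicate aggregation with significance testing into report tables.
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
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
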