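Package: voxeldamage
Title: Semi-Empirical Modelling of Radiation-Induced Clustered DNA Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale stochastic surrogate for track-structure modelling of
    clustered DNA damage in nanometric volumes of hydrated DNA. Electron, proton
    and alpha-particle tracks traversing 36 nm^3 voxels (15 base pairs plus
    hydration shell) are converted into ionization counts, low-energy electron
    (LEE) spectra and water-radiolysis G-values as functions of track-averaged
    LET, and then into single-strand break, double-strand break and base-lesion
    tallies through experimentally measured yields and cross-sections. At the
    cell-nucleus scale the package scores damage sites and cluster size for a
    fixed deposited energy (260 keV in a 4 micrometre nucleus, equivalent to
    2 Gy), exposing the trade-off between particle LET and fluence. All model
    constants carry provenance tags and the calibration layer is serialisable.
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
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
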