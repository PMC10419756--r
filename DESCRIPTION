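Package: bnmi
Title: Binning-Normalized Mutual Information Wavelength Selection for
    Near-Infrared Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wavelength (variable) selection for multivariate near-infrared
    calibration by binning-normalized mutual information (B-NMI): equal-interval
    discretization of absorbance and reference values, ranking of wavelengths by
    normalized mutual information (symmetrical uncertainty) against the
    reference property, and forward accumulation of ranked wavelengths into a
    partial least squares model with exhaustive enumeration of the bin count.
    Includes the five classical baseline selectors it is usually compared with
    (correlation coefficient, VIP, UVE, CARS, backward-interval PLS), a SIMPLS
    partial least squares engine with leave-one-out cross-validation,
    Kennard-Stone sample splitting, SNV and mean-centering preprocessing,
    F-test model comparison, and a Beer-Lambert synthetic mixture generator
    with ground-truth informative bands for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
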