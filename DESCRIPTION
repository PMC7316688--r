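Package: speclight
Title: Light-Source Calibration for Multispectral Imaging via Specular Highlights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the illuminant spectrum seen by a multispectral camera
    from the specular highlights of low-exposure images, with automatic
    exposure selection through a goodness metric, four classical model-based
    baseline estimators (max-band, gray-world, shades-of-gray, gray-edge)
    extended to multispectral cubes, a layered-tissue forward model and
    dichromatic scene simulator for in silico validation, and an
    illuminant-adapted random-forest pipeline quantifying the downstream
    benefit of calibration for tissue oxygenation estimation.
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
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
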