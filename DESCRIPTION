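Package: carborne
Title: Car-Borne Gamma-Ray Survey Analysis and Natural Radionuclide Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for car-borne NaI(Tl) gamma-ray surveys of
    terrestrial natural radiation. Simulates and unfolds 1024-channel
    pulse-height spectra into 40K, 238U-series and 232Th-series activity
    concentrations using a 22x22 response matrix with diagonal-elements
    re-broadening, builds unit-activity flux libraries for a semi-infinite
    ground source by seeded 1-D Monte Carlo transport, converts vehicle count
    rates to outdoor air kerma via shielding and dose-rate conversion factors,
    derives annual effective doses, and produces regional dose summaries and
    gridded dose maps. Includes a synthetic-data generator for spot spectra
    and survey tracks over heterogeneous activity fields with coastal
    thorium hotspots.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
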