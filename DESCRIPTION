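Package: mineralkin
Title: Kinetic Analysis of 14C-Labelled Mineralization Curves from Soil Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits single first-order (SFO), first-order multi-compartment
    (Gustafson-Holden, FOMC) and biphasic hockey-stick (HS) kinetic models to
    cumulative 14CO2 mineralization curves from soil respirometry experiments,
    computes dissipation times (DT50/DT90) by closed form and by numeric root
    finding, scores fits with the FOCUS chi-square error criterion, and selects
    the best model per soil and treatment. Includes a synthetic respirometry
    generator emulating triplicate alkali-trap time series for bioremediation
    treatment comparisons (biostimulation, bioaugmentation, cyclodextrin
    bioavailability enhancement), tidy table and report writers, and helpers
    for serial-dilution CFU counts, extractability percentages and
    hydroxypropyl-beta-cyclodextrin dosing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
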