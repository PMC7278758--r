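Package: dairysim
Title: Energy-Balance Simulation of Stall-Fed Dairy Cattle in the (Sub-)Tropics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly time-step simulator of growth, lactation, feed intake
    and metabolizable-energy partitioning for stall-fed dairy cattle under
    (sub-)tropical feeding conditions.  Potential growth follows a
    parameterized Gompertz curve, potential milk yield a two-parameter
    lactation curve, and nutrient requirements a factorial metabolizable
    energy (ME) and utilizable crude protein (uCP) scheme with age-dependent
    costs of body-weight gain.  Voluntary dry-matter intake blends a physical
    (neutral detergent fiber capacity) and a physiological (ME demand)
    regulation term, down-scaled by a body-weight condition index.  A
    partitioning sub-module allocates ME intake among maintenance, activity,
    gestation, milk and gain, with capped mobilization of body reserves in
    early lactation.  Model-adequacy statistics (mean bias error, root mean
    squared error of prediction, relative prediction error) and an evaluation
    harness against observed stall-fed dairy performance are included.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
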