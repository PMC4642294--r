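Package: pamdensity
Title: Cue-Count and Group-Count Density Estimation from Passive Acoustic
    Monitoring of Beaked Whales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates weekly animal densities of deep-diving odontocetes
    (beaked whales) from fixed passive acoustic monitoring records. Turns
    click-detection logs and recording-effort tables into weekly click counts
    and 5-minute group-presence counts, estimates the behavioural multipliers
    (modal inter-click interval and click production rate, proportion of time
    clicking, group size, group vocal-activity probability with synchrony),
    simulates click and group detection probability with a Monte Carlo
    sonar-equation model (spherical spreading, seawater absorption, piston
    beam pattern), and combines them into cue-count and group-count density
    estimates with delta-method variance and lognormal confidence intervals.
    Includes a synthetic-data generator with a known ground-truth density so
    that the full pipeline is testable end to end.
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
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    readr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
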