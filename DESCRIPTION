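Package: dielPAM
Title: Diel Activity Analysis of Passive Acoustic Click-Minute Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for year-round passive acoustic monitoring
    records of odontocete echolocation clicks exported as clicks detected
    per minute. Segments the record into light and dark periods from an
    internal NOAA-style solar ephemeris, summarises each period by its
    median clicks per minute, tests diel, crepuscular, lunar-phase and
    water-level effects with label-randomisation tests on median
    differences, and estimates the peak clicking time of day with weighted
    circular statistics (Rayleigh test, von Mises maximum likelihood with
    a confidence interval for the mean direction). Includes a synthetic
    data generator that simulates a year of overdispersed minute counts
    with night-elevated rates, sunrise/sunset activity bumps, seasonal
    modulation, tide-like water levels and logger gaps, with the
    generating truth retained for recovery tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
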