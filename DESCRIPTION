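Package: seasonsync
Title: Seasonal Variation in Hospitalization Outcomes and
    Intervention-Synchronized Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates calendar-month seasonal variation in hospitalization
    outcomes (admission counts and length of stay) from multi-year
    patient-level admission records by linear detrending of 36-month outcome
    series and averaging percentage deviations from the fitted baseline into
    per-climate-zone seasonal profiles. Implements the synchronized seasonal
    profile, which pools each patient's expected seasonal deviation by months
    since intervention commencement to attenuate seasonal confounding in
    pre/post telemonitoring comparisons, and a Monte-Carlo comparison of
    recruitment-date distributions (observed, Poisson-rate, discrete uniform).
    Includes a synthetic cohort generator with known seasonal structure, an
    aging trend, and configurable recruitment schedules, plus seasonal
    summary tables and between-season significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
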