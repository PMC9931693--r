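Package: chinooklipid
Title: Fat-Meter Calibration and Stock-Specific Lipid Analysis for Fraser River Chinook Salmon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates handheld microwave fat-meter readings to whole-body
    lipid content of Chinook salmon via continuous piecewise (segmented) and
    model II (major-axis and standardized major-axis) regression, converts
    lipid content to energy density, and analyses stock-specific and seasonal
    variation in lipid levels across Fraser River Chinook management units:
    run-timing summaries, ANOVA with Tukey letter groupings, seasonal lipid
    trends and slope comparisons, hatchery-wild contrasts, weekly
    catch-per-unit-effort aggregation, migration-difficulty correlations, and
    killer-whale prey-requirement bioenergetics. Includes a seeded synthetic
    data generator emulating the calibration cohort and river-entry test
    fishery survey so the full pipeline is reproducible without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
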