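Package: hazemet
Title: Haze Episode Detection and Coastal Meteorology Typing for Urban PM2.5
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects haze days and haze episodes from multi-station hourly
    PM2.5 records, classifies sea-breeze days from surface winds and land-sea
    thermal contrast, computes the daytime wind recirculation factor, assigns
    each episode one of four meteorology-based haze types (cold-surge
    influenced, sea-breeze influenced, synergistic, or neither), and screens
    episodes for secondary-aerosol influence with CO-normalized precursor
    ratios. Includes a synthetic multi-station scenario generator with planted
    ground truth so every stage of the pipeline can be exercised and validated
    without access to agency data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
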