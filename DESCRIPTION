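Package: pmexposure
Title: Personal PM2.5 Exposure Assessment with Time-Weighted Average Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates daily personal PM2.5 exposure by fusing a dense
    low-cost sensor network (interpolated to a regular grid by ordinary
    kriging), GPS trajectories, 30-minute time-activity diaries, home
    indoor monitors and hourly microenvironment concentration models into
    three time-weighted-average exposure scenarios, with indoor/outdoor
    contribution decomposition and estimator evaluation against personal
    monitor measurements. Includes a synthetic panel-study generator that
    reproduces the qualitative structure of urban exposure data (commute
    corridors, indoor peak events, infiltration) so the whole pipeline is
    testable without restricted panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ranger,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
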