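Package: macroscreen
Title: Analysis of Macropinocytosis-Dependent Growth Compound Screens
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for plate-based compound viability screens of
    macropinocytosis-dependent growth: per-plate normalization of raw
    luminescence to DMSO vehicle wells, model-free dose-response AUC scoring
    on a linear concentration axis, screen-wide mean +/- SD hit calling with
    EIPA/Torin1 control-compound quality gates, aggregation of hits by
    annotated target, and a synthetic screen generator with Hill-shaped
    planted effects for end-to-end validation without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
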