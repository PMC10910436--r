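Package: chromacc
Title: Accommodation, Chromatic Aberration, and Acuity Under Narrowband Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for steady-state ocular accommodation measured by
    photorefraction under narrowband illuminants. Implements the hyperbolic
    chromatic eye model and trial-lens optics, cleaning of 50 Hz
    refraction/pupillometry traces (blink masking, refraction limits, onset
    trimming, per-subject calibration), stimulus-response-curve statistics
    (gradient-based saturation detection, within-trial RMSE variability),
    linear mixed-effects analyses of LCA compensation, response variability,
    pupil size, and visual acuity, a best-PEST adaptive staircase for 4AFC
    Landolt-C acuity, and a seeded synthetic-data generator that emulates the
    statistical structure of such experiments for testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    emmeans,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
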