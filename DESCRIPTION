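Package: growthlag
Title: Logistic Growth-Curve Fitting, Lag-Phase Statistics and Per-Cell
    One-Carbon Budgets for Plate-Reader Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how supplements shift the bacterial lag
    phase in 96-well plate-reader experiments. Reads long or wide
    plate-reader exports, applies instrument calibration and per-well
    background subtraction, fits the logistic growth model by
    least squares, and extracts lag times (time to a fixed optical
    density threshold) and doubling times in closed form. Between-condition
    lag differences are summarised with propagated standard deviations and
    tested against a single control with Dunnett's many-to-one procedure.
    Also included: a per-cell stoichiometric budget of assimilatory
    one-carbon (C1) groups and dissimilatory ATP with percent coverage by
    an external methylated compound, expression-table filters (TPM
    conversion, top-k abundance ranking, differential-expression and
    abundance thresholds), and a synthetic-data generator with closed-form
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    multcomp,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
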