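Package: arval
Title: Agreement Analysis for Smartphone AR Head-Tracking Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses paired head-trajectory recordings from a
    smartphone augmented-reality training game (30 Hz pose log) and an
    optoelectronic motion-capture reference (120 Hz marker trajectories).
    Provides trajectory file I/O and marker-based rigid pose reconstruction,
    cross-correlation time synchronization on a head-nod landmark, coordinate
    frame registration, exercise repetition segmentation with height-scaled
    thresholds, and the full method-comparison statistics battery: mean
    absolute difference, RMSE, mean absolute relative difference, Spearman
    rank correlation, ICC(2,1) with confidence interval, Lilliefors-corrected
    Kolmogorov-Smirnov normality test, non-parametric Bland-Altman limits of
    agreement, and Fisher-z sample-size calculation.
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
    withr,
    optparse
Config/testthat/edition: 3
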