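Package: sharedgain
Title: Shared Gain Modulation Analysis for Visual Cortical Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing running-correlated modulation of
    primary visual cortex (V1) population activity across species. Provides
    orientation tuning curves and selectivity indices for drifting-grating
    responses, session-level correlation of the leading neural principal
    component with running speed with circular-shift permutation significance,
    unit-level running/stationary modulation ratios with bootstrap inference,
    a shared multiplicative-gain latent-variable model for trial spike counts
    fitted with speckled-holdout cross-validation, regression-based estimates
    of saccade-attributable firing-rate changes, and a synthetic-session
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
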