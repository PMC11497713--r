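Package: adtimesave
Title: Long-Term Efficacy Scenarios for Amyloid-Targeting Therapies on
    the CDR-SB Natural History Timeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the long-term efficacy of
    amyloid-targeting therapies in Alzheimer's disease. Trial-level
    summary trajectories of the Clinical Dementia Rating-Sum of Boxes
    (CDR-SB) are anchored on a long-term natural-history trajectory of
    the disease (time since amyloid-PET positivity), the time delay and
    time saving at the final trial visit are estimated from the placebo
    trajectory by spline interpolation, and the active arm is
    extrapolated beyond the trial under three scenarios (enduring delay,
    fading slowing, continued slowing) to compute treatment-associated
    delays in reaching severe dementia (CDR-SB 16). Includes a
    mixed-effects natural-cubic-spline fitter for the natural-history
    mean trajectory and synthetic-data generators for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
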