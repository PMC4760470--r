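Package: dpps
Title: Geometric Modelling of Defensive Peripersonal Space from Blink-Reflex Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models defensive peripersonal space (DPPS) as the region around the
    head where the probability of being hit by a threat, estimated by Monte-Carlo
    solid-angle ray casting against candidate defended-area geometries (clipped
    ellipsoids), predicts the enhancement of the hand-blink reflex (HBR). Provides
    the full analysis pipeline: a synthetic trial-level study generator over six
    experimental hand-position layouts, normalization of trial-level EMG
    area-under-curve magnitudes onto a common scale (eye pooling, fourth-root
    transform, per-subject anchoring, cross-experiment rescaling, distributional
    gating), chi-square fitting of the linear response model S(r) = a*P(c_grav, r)
    + b per geometry with goodness-of-fit model comparison, gravity-biased
    trajectory sampling, gridded response fields, and cutoff-based DPPS region
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
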