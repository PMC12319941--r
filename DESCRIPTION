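Package: navaff
Title: Split-Half Euclidean-Distance Decoding of Navigational Affordance
    and Ego-Motion fMRI Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for ROI-based analysis of
    navigational-affordance and ego-motion coding in scene-selective visual
    cortex. Generates complete synthetic event-related fMRI experiments
    (10-condition affordance-by-ego-motion design, counterbalanced room
    textures, lateralized effect structure with known ground truth),
    estimates condition responses with an event-related GLM (boxcars
    convolved with a double-gamma HRF, discrete-cosine high-pass, OLS),
    selects fixed-size functional ROIs as top-N voxels under a localizer
    contrast, performs split-half cross-validated Euclidean-distance
    decoding under condition-structured hypothesis matrices, computes
    hemisphere-resolved (contralateral vs ipsilateral) univariate
    contrasts, and runs group inference (paired t-tests, repeated-measures
    ANOVA with Greenhouse-Geisser correction, noncentral-t power).
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
    purrr,
    readr,
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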