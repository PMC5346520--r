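Package: waveclass
Title: Multimodal Single-Subject Classification with Weight-Adjusted
    Voting Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-subject classification of psychiatric
    diagnostic status from multimodal biobehavioral data: linear
    support-vector-machine classification of clinical questionnaire
    scores, salivary cortisol release (log-transformed area under the
    curve with respect to the ground) and voxel-based gray- and
    white-matter volume maps under leave-one-out cross-validation with
    permutation significance testing, fused across modalities by a
    weight-adjusted voting ensemble (WAVE) inside a nested
    cross-validation scheme. Includes a calibrated synthetic cohort
    generator emulating a matched anxiety/depression/control sample so
    the full pipeline is testable without clinical data, plus one-way
    ANOVA and chi-square utilities for cohort description tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
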