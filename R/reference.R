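#' Bundled reference result tables
#'
#' Small plain-text tables distributed with the package describing the
#' reference multimodal GAD/MD/HC analysis that the synthetic generator is
#' calibrated against: per-modality classification performance
#' (`reference_performance()`: sensitivity and specificity percentages for
#' both diagnostic problems, single modalities and the WAVE fusion),
#' questionnaire weight averages (`reference_clinical_weights()`) and
#' regional GM weight averages with voxel counts
#' (`reference_region_weights()`). They serve as worked inputs for the
#' summary arithmetic -- balanced accuracy from sensitivity/specificity,
#' weight percentages from absolute weight averages -- and as plausibility
#' anchors in the test suite.
#'
#' @return A tibble.
#' @examples
#' perf <- reference_performance()
#' balanced_accuracy(perf$sensitivity, perf$specificity)
#' @export
reference_performance <- function() {
  read_reference("reference_performance.tsv")
}

#' @rdname reference_performance
#' @export
reference_clinical_weights <- function() {
  read_reference("reference_clinical_weights.tsv")
}

#' @rdname reference_performance
#' @export
reference_region_weights <- function() {
  read_reference("reference_region_weights.tsv")
}

read_reference <- function(name) {
  path <- system.file("extdata", name, package = "waveclass", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
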