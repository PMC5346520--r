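#' Default generative parameters for the reference cohort
#'
#' Per-group questionnaire score distributions (sum-score mean and SD for the
#' PSWQ, BDI-II, IUS-12 and trait STAI), age distributions, demographic
#' category counts and log-AUC cortisol release distributions describing a
#' matched cohort of 24 healthy controls (HC), 19 subjects with generalized
#' anxiety disorder (GAD, 12 of them with comorbid major depression) and 14
#' subjects with major depression without GAD (MD). These summaries calibrate
#' the synthetic generator so that cohorts it emits carry the group structure
#' the classification pipeline assumes.
#'
#' @return A tibble with columns `group`, `scale`, `mean`, `sd`.
#' @seealso [cohort_config()]
#' @export
default_questionnaire_params <- function() {
  tibble::tribble(
    ~group, ~scale,  ~mean, ~sd,
    "HC",  "pswq",  36.00,  9.98,
    "GAD", "pswq",  62.00,  6.22,
    "MD",  "pswq",  57.43, 12.06,
    "HC",  "bdi",    4.50,  4.82,
    "GAD", "bdi",   21.16,  7.37,
    "MD",  "bdi",   21.36,  9.14,
    "HC",  "ius12", 25.75,  6.72,
    "GAD", "ius12", 41.00,  7.03,
    "MD",  "ius12", 32.71,  9.25,
    "HC",  "stait", 33.58,  6.77,
    "GAD", "stait", 56.16,  7.11,
    "MD",  "stait", 55.00,  7.04
  )
}

#' @rdname default_questionnaire_params
#' @export
default_cortisol_params <- function() {
  tibble::tribble(
    ~group, ~mean,  ~sd,
    "HC",  199.55, 66.05,
    "GAD", 159.85, 38.76,
    "MD",  196.61, 70.30
  )
}

#' @rdname default_questionnaire_params
#' @export
default_age_params <- function() {
  tibble::tribble(
    ~group, ~mean,  ~sd,
    "HC",  32.25,  9.33,
    "GAD", 33.47,  8.90,
    "MD",  29.86, 11.71
  )
}

#' @rdname default_questionnaire_params
#' @export
default_demographic_counts <- function() {
  tibble::tribble(
    ~group, ~female, ~right_handed, ~secondary_school, ~nonsmoker,
    "HC",   17,      21,            18,                22,
    "GAD",  16,      17,            12,                19,
    "MD",   12,      11,            12,                13
  )
}

# Plausible instrument sum-score ranges used to clip generated scores.
instrument_ranges <- function() {
  tibble::tribble(
    ~scale,  ~min, ~max,
    "pswq",  16,   80,
    "bdi",    0,   63,
    "ius12", 12,   60,
    "stait", 20,   80
  )
}

#' Default regional volume effects
#'
#' The default effect table places opposite frontal gray-matter volume shifts
#' in the two clinical groups: a multiplicative increase in all frontal
#' regions for GAD and a decrease of the same magnitude for MD, consistent
#' with the morphometry literature on the two disorders. White matter carries
#' no group effect by default.
#'
#' @param gm_effect Multiplicative frontal GM shift (default 0.05, i.e. 5%).
#' @return A tibble with columns `tissue`, `region`, `group`, `effect`.
#' @export
default_effect_table <- function(gm_effect = 0.05) {
  frontal <- grep("frontal", atlas_region_names(), value = TRUE)
  dplyr::bind_rows(
    tibble::tibble(tissue = "gm", region = frontal, group = "GAD",
                   effect = gm_effect),
    tibble::tibble(tissue = "gm", region = frontal, group = "MD",
                   effect = -gm_effect)
  )
}

#' Configure a synthetic multimodal cohort
#'
#' Builds the parameter object consumed by [simulate_cohort()]. Defaults
#' describe the reference cohort (57 subjects in three matched groups, four
#' questionnaires, six timed saliva samples spanning 100 minutes, and smooth
#' voxelwise tissue-volume maps on a 40 x 48 x 40 grid of 3 mm voxels with
#' frontal GM effects in opposite directions for the two clinical groups).
#'
#' @param group_sizes Named integer vector of group sizes (HC, GAD, MD).
#' @param n_comorbid Number of GAD subjects also meeting criteria for MD.
#' @param questionnaire_params Tibble `group`, `scale`, `mean`, `sd`.
#' @param age_params Tibble `group`, `mean`, `sd` of age in years.
#' @param demographic_counts Tibble of per-group category counts (see
#'   [default_demographic_counts()]); counts are realized exactly, not
#'   sampled.
#' @param cortisol_params Tibble `group`, `mean`, `sd` of the target
#'   log-AUC (natural-log units x minutes) of total cortisol release.
#' @param cortisol_shape_sd SD (log units) of the zero-area wiggle added to
#'   each profile around its release level.
#' @param sample_times Saliva sampling times in minutes; strictly increasing,
#'   six by default, spanning 100 minutes.
#' @param grid_shape Integer length-3 voxel counts of the image grid.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param effect_table Tibble `tissue`, `region`, `group`, `effect` of
#'   multiplicative regional volume shifts (see [default_effect_table()]).
#' @param noise_sd Marginal SD of the smoothed voxelwise noise field, on the
#'   scale of the tissue-volume values (baselines 0.5 GM / 0.4 WM).
#' @param subject_sd SD of the per-subject global volume scaling factor
#'   (multiplicative, mean 1), emulating between-subject brain-size variation.
#' @param smoothing_fwhm_mm Full width at half maximum of the Gaussian kernel
#'   applied to the voxel noise field, in mm.
#' @param gm_baseline,wm_baseline Baseline tissue-volume values.
#' @param missing_cortisol Number of subjects given an incomplete cortisol
#'   profile (one missing sample each).
#' @param missing_smoking Number of HC subjects with missing smoking status.
#' @param modalities Character subset of `c("clinical", "cortisol", "gm",
#'   "wm")` to generate; restricting this speeds up replicate simulations
#'   that only exercise tabular modalities.
#' @param seed Integer RNG seed; the cohort is fully reproducible given the
#'   configuration and seed.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(seed = 7, modalities = "clinical")
#' cohort <- simulate_cohort(cfg)
#' dplyr::count(cohort$subjects, group)
#' @export
cohort_config <- function(group_sizes = c(HC = 24, GAD = 19, MD = 14),
                          n_comorbid = 12,
                          questionnaire_params = default_questionnaire_params(),
                          age_params = default_age_params(),
                          demographic_counts = default_demographic_counts(),
                          cortisol_params = default_cortisol_params(),
                          cortisol_shape_sd = 0.25,
                          sample_times = c(0, 10, 35, 55, 75, 100),
                          grid_shape = c(40L, 48L, 40L),
                          voxel_size_mm = 3.0,
                          effect_table = default_effect_table(),
                          noise_sd = 0.05,
                          subject_sd = 0.05,
                          smoothing_fwhm_mm = 8,
                          gm_baseline = 0.5,
                          wm_baseline = 0.4,
                          missing_cortisol = 1,
                          missing_smoking = 1,
                          modalities = c("clinical", "cortisol", "gm", "wm"),
                          seed = 1L) {
  cfg <- list(
    group_sizes = group_sizes, n_comorbid = n_comorbid,
    questionnaire_params = tibble::as_tibble(questionnaire_params),
    age_params = tibble::as_tibble(age_params),
    demographic_counts = tibble::as_tibble(demographic_counts),
    cortisol_params = tibble::as_tibble(cortisol_params),
    cortisol_shape_sd = cortisol_shape_sd,
    sample_times = sample_times,
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    effect_table = tibble::as_tibble(effect_table),
    noise_sd = noise_sd, subject_sd = subject_sd,
    smoothing_fwhm_mm = smoothing_fwhm_mm,
    gm_baseline = gm_baseline, wm_baseline = wm_baseline,
    missing_cortisol = missing_cortisol,
    missing_smoking = missing_smoking,
    modalities = match.arg(modalities, c("clinical", "cortisol", "gm", "wm"),
                           several.ok = TRUE),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  assert_that(all(c("HC", "GAD", "MD") %in% names(cfg$group_sizes)),
              "group_sizes must name HC, GAD and MD")
  assert_that(all(cfg$group_sizes > 0), "all group sizes must be positive")
  assert_that(cfg$n_comorbid >= 0 && cfg$n_comorbid <= cfg$group_sizes[["GAD"]],
              "n_comorbid must be between 0 and the GAD group size")
  assert_that(!is.unsorted(cfg$sample_times, strictly = TRUE),
              "sample_times must be strictly increasing")
  assert_that(length(cfg$sample_times) >= 2, "need at least two sample times")
  assert_that(all(cfg$questionnaire_params$sd > 0), "questionnaire SDs must be > 0")
  assert_that(all(cfg$cortisol_params$sd > 0), "cortisol SDs must be > 0")
  assert_that(length(cfg$grid_shape) == 3 && all(cfg$grid_shape > 0),
              "grid_shape must be three positive integers")
  assert_that(cfg$noise_sd >= 0 && cfg$subject_sd >= 0, "noise SDs must be >= 0")
  dc <- cfg$demographic_counts
  for (g in c("HC", "GAD", "MD")) {
    row <- dc[dc$group == g, c("female", "right_handed", "secondary_school",
                               "nonsmoker")]
    assert_that(nrow(row) == 1 && all(unlist(row) <= cfg$group_sizes[[g]]),
                sprintf("demographic counts for %s exceed the group size", g))
  }
  assert_that(cfg$missing_cortisol >= 0 &&
                cfg$missing_cortisol <= sum(cfg$group_sizes),
              "missing_cortisol out of range")
  invisible(cfg)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' Reads a file of [cohort_config()] arguments. Scalar fields map directly;
#' `group_sizes` must be a named mapping and the `*_params`,
#' `demographic_counts` and `effect_table` fields tables (lists of columns
#' or row records). Fields absent from the file keep their defaults.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` needs
#'   the yaml package, anything else is parsed as JSON).
#' @return A `cohort_config`.
#' @export
cohort_config_from_file <- function(path) {
  assert_that(file.exists(path), sprintf("no such config file '%s'", path),
              class = "waveclass_io")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_waveclass("reading YAML configs requires the yaml package",
                     "waveclass_io")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  tabular <- c("questionnaire_params", "age_params", "demographic_counts",
               "cortisol_params", "effect_table")
  for (f in intersect(tabular, names(raw))) {
    raw[[f]] <- tibble::as_tibble(dplyr::bind_rows(raw[[f]]))
  }
  if ("group_sizes" %in% names(raw)) {
    raw$group_sizes <- unlist(raw$group_sizes)
  }
  unknown <- setdiff(names(raw), names(formals(cohort_config)))
  assert_that(length(unknown) == 0,
              sprintf("unknown config fields: %s",
                      paste(unknown, collapse = ", ")))
  do.call(cohort_config, raw)
}

#' Null-cohort configuration
#'
#' A configuration with no systematic group separation in any modality: all
#' groups share the HC questionnaire, age and cortisol distributions and the
#' effect table is empty. Used for calibration checks of permutation tests
#' (downstream classifiers should sit at chance).
#'
#' @inheritParams cohort_config
#' @param ... Passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(seed = 1L, ...) {
  qp <- default_questionnaire_params()
  hc <- dplyr::filter(qp, .data$group == "HC")
  qp <- dplyr::bind_rows(lapply(c("HC", "GAD", "MD"), function(g) {
    dplyr::mutate(hc, group = g)
  }))
  cp <- tibble::tibble(group = c("HC", "GAD", "MD"), mean = 199.55, sd = 66.05)
  ap <- tibble::tibble(group = c("HC", "GAD", "MD"), mean = 32.25, sd = 9.33)
  cohort_config(questionnaire_params = qp, cortisol_params = cp,
                age_params = ap,
                effect_table = default_effect_table(0)[0, ],
                seed = seed, ...)
}

#' Effect-loaded cohort configuration
#'
#' The reference configuration with strong biological group contrasts layered
#' on top of the calibrated questionnaire distributions: a widened cortisol
#' release gap between GAD (low) and MD (high) and stronger opposite-signed
#' frontal GM shifts. Under this configuration the expected qualitative
#' pattern is that clinical scores dominate case-classification (disorder vs
#' control) while cortisol and GM dominate disorder-classification (GAD vs
#' MD).
#'
#' @inheritParams cohort_config
#' @param gm_effect Frontal GM multiplicative shift (default 0.08).
#' @param ... Passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
strong_effect_config <- function(seed = 1L, gm_effect = 0.08, ...) {
  cp <- tibble::tribble(
    ~group, ~mean,  ~sd,
    "HC",  199.55, 66.05,
    "GAD", 150.00, 35.00,
    "MD",  215.00, 45.00
  )
  cohort_config(cortisol_params = cp,
                effect_table = default_effect_table(gm_effect),
                seed = seed, ...)
}
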