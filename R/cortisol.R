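#' Area under a log-transformed cortisol curve, with respect to ground
#'
#' Log-transforms each saliva cortisol concentration and integrates the
#' resulting curve over the actual sampling grid with the trapezoidal rule,
#' measured from zero ("with respect to the ground"), the standard aggregate
#' measure of total hormone release over a sampling window:
#' \deqn{AUC_g = \sum_i \frac{\log v_{i+1} + \log v_i}{2}\,(t_{i+1} - t_i).}
#' Only the sampling intervals matter, so any clock-time origin is
#' acceptable. The log transform is natural by default; the magnitude of the
#' resulting feature over a 100-minute window with concentrations in nmol/L
#' is then on the order of 150--250 log-units x min.
#'
#' @param times Sampling times in minutes, strictly increasing.
#' @param values Cortisol concentrations (nmol/L), positive, same length.
#' @param log_base Base of the log transform (default `exp(1)`).
#' @return The log-AUC (scalar).
#' @examples
#' log_auc_ground(c(0, 100), c(exp(1), exp(1)))  # 100
#' @export
log_auc_ground <- function(times, values, log_base = exp(1)) {
  assert_that(length(times) == length(values) && length(times) >= 2,
              "times and values must have equal length >= 2")
  assert_that(!anyNA(times) && !is.unsorted(times, strictly = TRUE),
              "times must be strictly increasing")
  assert_that(!anyNA(values), "profile is incomplete (missing values)",
              class = "waveclass_incomplete")
  assert_that(all(values > 0), "cortisol values must be positive",
              class = "waveclass_domain")
  trapz(times, log(values, base = log_base))
}

#' Cortisol release features for a cohort
#'
#' Computes the per-subject log-AUC release feature from a long table of
#' timed saliva samples, screening out incomplete profiles (fewer than
#' `n_samples` samples, or any missing/nonpositive value). Subjects excluded
#' here must also be excluded from all other modalities before ensemble
#' fusion, which [multimodal_features()] does automatically.
#'
#' @param data Long tibble with columns `subject_id`, `time_min`,
#'   `cortisol_nmol_l`.
#' @param n_samples Number of samples a complete profile must have.
#' @inheritParams log_auc_ground
#' @return A list with `features` (tibble `subject_id`, `log_auc`, complete
#'   profiles only) and `excluded_ids` (character).
#' @examples
#' d <- tibble::tibble(subject_id = "a", time_min = c(0, 10),
#'                     cortisol_nmol_l = exp(c(2, 4)))
#' screen_profiles(d, n_samples = 2)$features
#' @export
screen_profiles <- function(data, n_samples = 6, log_base = exp(1)) {
  assert_that(all(c("subject_id", "time_min", "cortisol_nmol_l") %in% names(data)),
              "data must have subject_id, time_min, cortisol_nmol_l columns")
  split_d <- split(data, data$subject_id)
  ids <- names(split_d)
  complete <- vapply(split_d, function(d) {
    nrow(d) == n_samples && !anyNA(d$cortisol_nmol_l) &&
      all(d$cortisol_nmol_l > 0)
  }, logical(1))
  feats <- purrr::map_dfr(split_d[complete], function(d) {
    d <- d[order(d$time_min), ]
    tibble::tibble(subject_id = d$subject_id[1],
                   log_auc = log_auc_ground(d$time_min, d$cortisol_nmol_l,
                                            log_base = log_base))
  })
  if (nrow(feats) == 0) {
    feats <- tibble::tibble(subject_id = character(0), log_auc = numeric(0))
  }
  list(features = feats, excluded_ids = ids[!complete])
}
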