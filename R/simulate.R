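#' Simulate a multimodal cohort
#'
#' Generates a complete synthetic cohort with the statistical structure the
#' classification pipeline assumes: a subjects table with exact group sizes,
#' comorbidity bookkeeping and demographics realized as exact category
#' counts; questionnaire sum scores drawn from per-group truncated normals;
#' timed saliva cortisol profiles whose log-AUC follows the configured
#' per-group normal exactly by construction; and smooth nonnegative GM/WM
#' volume maps with region-localized multiplicative group effects on a
#' shared grid with a box-parcel atlas.
#'
#' @param config A [cohort_config()].
#' @return An object of class `wave_cohort`: list with `subjects` (tibble),
#'   `cortisol` (long tibble `subject_id`, `time_min`, `cortisol_nmol_l`),
#'   `gm`/`wm` (named lists of 3D arrays, one per subject), `atlas`
#'   ([build_synthetic_atlas()] object), `grid`, `truth` (effect metadata)
#'   and `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7, modalities = "clinical"))
#' nrow(cohort$subjects)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    subjects <- simulate_subjects(config)
    cohort <- list(subjects = subjects)
    if ("cortisol" %in% config$modalities) {
      cohort$cortisol <- simulate_cortisol(subjects, config)
    }
    if (any(c("gm", "wm") %in% config$modalities)) {
      atlas <- build_synthetic_atlas(config$grid_shape, config$voxel_size_mm)
      imgs <- simulate_images(subjects, atlas, config)
      cohort$atlas <- atlas
      cohort$gm <- if ("gm" %in% config$modalities) imgs$gm
      cohort$wm <- if ("wm" %in% config$modalities) imgs$wm
      cohort$truth <- imgs$truth
    }
    cohort$grid <- list(shape = config$grid_shape,
                        voxel_size_mm = config$voxel_size_mm)
    cohort$config <- config
    structure(cohort, class = "wave_cohort")
  })
}

simulate_subjects <- function(config) {
  sizes <- config$group_sizes[c("HC", "GAD", "MD")]
  group <- factor(rep(names(sizes), sizes), levels = c("HC", "GAD", "MD"))
  n <- length(group)
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    comorbid_md = FALSE
  )
  gad_idx <- which(group == "GAD")
  subjects$comorbid_md[sample(gad_idx, config$n_comorbid)] <- TRUE

  # Demographics: exact category counts per group, shuffled within group.
  counts <- config$demographic_counts
  fill_cat <- function(col, yes, no) {
    out <- character(n)
    for (g in names(sizes)) {
      idx <- which(group == g)
      k <- counts[[col]][counts$group == g]
      v <- c(rep(yes, k), rep(no, length(idx) - k))
      out[idx] <- sample(v)
    }
    out
  }
  subjects$sex <- fill_cat("female", "female", "male")
  subjects$handedness <- fill_cat("right_handed", "right", "left")
  subjects$education <- fill_cat("secondary_school", "secondary", "other")
  subjects$smoker <- fill_cat("nonsmoker", "no", "yes")
  if (config$missing_smoking > 0) {
    hc_non <- which(group == "HC" & subjects$smoker == "no")
    subjects$smoker[sample(hc_non, min(config$missing_smoking, length(hc_non)))] <- NA
  }

  ages <- numeric(n)
  for (g in names(sizes)) {
    ap <- config$age_params[config$age_params$group == g, ]
    idx <- which(group == g)
    ages[idx] <- round(pmin(60, pmax(18, rnorm(length(idx), ap$mean, ap$sd))))
  }
  subjects$age <- ages

  rng <- instrument_ranges()
  for (sc in c("pswq", "bdi", "ius12", "stait")) {
    lim <- rng[rng$scale == sc, ]
    v <- numeric(n)
    for (g in names(sizes)) {
      qp <- config$questionnaire_params[
        config$questionnaire_params$group == g &
          config$questionnaire_params$scale == sc, ]
      assert_that(nrow(qp) == 1,
                  sprintf("questionnaire_params missing %s/%s", g, sc))
      idx <- which(group == g)
      v[idx] <- round(pmin(lim$max, pmax(lim$min, rnorm(length(idx), qp$mean, qp$sd))))
    }
    subjects[[sc]] <- as.integer(v)
  }
  subjects
}

# Profiles are exp(level + shape) where shape has zero trapezoidal area, so
# each subject's log-AUC equals its normal draw exactly.
simulate_cortisol <- function(subjects, config) {
  times <- config$sample_times
  span <- diff(range(times))
  n <- nrow(subjects)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- config$cortisol_params[
      config$cortisol_params$group == as.character(subjects$group[i]), ]
    target_auc <- rnorm(1, cp$mean, cp$sd)
    shape <- rnorm(length(times), 0, config$cortisol_shape_sd)
    shape <- shape - trapz(times, shape) / span
    logv <- target_auc / span + shape
    rows[[i]] <- tibble::tibble(subject_id = subjects$subject_id[i],
                                time_min = times,
                                cortisol_nmol_l = exp(logv))
  }
  cortisol <- dplyr::bind_rows(rows)
  if (config$missing_cortisol > 0) {
    miss <- sample(subjects$subject_id, config$missing_cortisol)
    for (id in miss) {
      drop_t <- sample(times, 1)
      cortisol <- cortisol[!(cortisol$subject_id == id &
                               cortisol$time_min == drop_t), ]
    }
  }
  cortisol
}

simulate_images <- function(subjects, atlas, config) {
  d <- atlas$grid$shape
  sigma_vox <- config$smoothing_fwhm_mm / (2 * sqrt(2 * log(2))) /
    config$voxel_size_mm
  gm_compartment <- atlas$brain_mask & !atlas$wm_mask
  wm_compartment <- atlas$wm_mask

  eff <- config$effect_table
  region_factor <- function(tissue, g) {
    f <- array(1, dim = d)
    rows <- eff[eff$tissue == tissue & eff$group == g, ]
    if (nrow(rows) == 0) return(f)
    for (r in seq_len(nrow(rows))) {
      labs <- atlas$table$label[atlas$table$region == rows$region[r]]
      f[atlas$labels %in% labs] <- f[atlas$labels %in% labs] * (1 + rows$effect[r])
    }
    f
  }
  gm_fac <- lapply(c("HC", "GAD", "MD"), function(g) region_factor("gm", g))
  names(gm_fac) <- c("HC", "GAD", "MD")
  wm_fac <- lapply(c("HC", "GAD", "MD"), function(g) region_factor("wm", g))
  names(wm_fac) <- c("HC", "GAD", "MD")

  make_noise <- function(compartment) {
    e <- gaussian_smooth_3d(array(rnorm(prod(d)), dim = d), sigma_vox)
    s <- stats::sd(e[compartment])
    e * (config$noise_sd / s)
  }

  gm <- wm <- list()
  subj_factor <- rnorm(nrow(subjects), 1, config$subject_sd)
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    g <- as.character(subjects$group[i])
    if ("gm" %in% config$modalities) {
      img <- array(0, dim = d)
      img[gm_compartment] <- config$gm_baseline
      img <- img * gm_fac[[g]] * subj_factor[i]
      img[gm_compartment] <- pmax(0, img[gm_compartment] +
                                    make_noise(gm_compartment)[gm_compartment])
      gm[[id]] <- img
    }
    if ("wm" %in% config$modalities) {
      img <- array(0, dim = d)
      img[wm_compartment] <- config$wm_baseline
      img <- img * wm_fac[[g]] * subj_factor[i]
      img[wm_compartment] <- pmax(0, img[wm_compartment] +
                                    make_noise(wm_compartment)[wm_compartment])
      wm[[id]] <- img
    }
  }
  truth <- list(effect_table = eff,
                region_sizes = atlas$table[, c("label", "region", "side", "n_voxels")],
                subject_factor = tibble::tibble(subject_id = subjects$subject_id,
                                                factor = subj_factor))
  list(gm = gm, wm = wm, truth = truth)
}

# Separable Gaussian blur of a 3D array (reflecting edges truncated at 4 sigma).
gaussian_smooth_3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  for (axis in 1:3) {
    K <- gauss_filter_matrix(d[axis], sigma_vox)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    m <- K %*% matrix(a, d[axis])
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  arr
}

gauss_filter_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + x
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  K
}
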