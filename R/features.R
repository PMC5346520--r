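#' Intersection mask across subjects
#'
#' Restricts voxelwise analyses to voxels for which every subject provides
#' data: a voxel is kept iff its value exceeds `threshold` in every image.
#'
#' @param images List of 3D arrays on a shared grid.
#' @param threshold Inclusion threshold (default 0, i.e. strictly positive
#'   tissue volume; VBM practice sometimes uses e.g. 0.01).
#' @return A 3D logical array.
#' @export
build_intersection_mask <- function(images, threshold = 0) {
  assert_that(length(images) >= 1, "need at least one image")
  d <- dim(images[[1]])
  for (img in images) {
    assert_that(identical(dim(img), d), "images are not on a shared grid",
                class = "waveclass_grid")
  }
  Reduce(`&`, lapply(images, function(img) img > threshold))
}

#' Select feature voxels under a region policy
#'
#' @param mask 3D logical intersection mask.
#' @param atlas A `roi_atlas` on the same grid.
#' @param roi_policy One of `"gm_rois"` (mask voxels inside the 30 labelled
#'   regions), `"wm_all"` (mask voxels inside the white-matter compartment)
#'   or `"whole_brain"` (all mask voxels; labelled voxels keep their region,
#'   others are tagged "Unlabelled").
#' @return Tibble with one row per selected voxel: `voxel` (linear index into
#'   the grid), `region`, `side`.
#' @export
select_roi_voxels <- function(mask, atlas,
                              roi_policy = c("gm_rois", "wm_all", "whole_brain")) {
  roi_policy <- match.arg(roi_policy)
  assert_that(identical(dim(mask), dim(atlas$labels)),
              "mask and atlas are not on a shared grid", class = "waveclass_grid")
  keep <- switch(roi_policy,
                 gm_rois = mask & atlas$labels > 0,
                 wm_all = mask & atlas$wm_mask,
                 whole_brain = mask)
  vox <- which(keep)
  assert_that(length(vox) > 0,
              sprintf("empty voxel selection under policy '%s'", roi_policy),
              class = "waveclass_empty")
  lab <- atlas$labels[vox]
  lut_region <- c("Unlabelled", atlas$table$region)[lab + 1L]
  lut_side <- c(NA_character_, atlas$table$side)[lab + 1L]
  if (roi_policy == "wm_all") {
    lut_region <- rep("White matter", length(vox))
    lut_side <- rep(NA_character_, length(vox))
  }
  tibble::tibble(voxel = vox, region = lut_region, side = lut_side)
}

#' Assemble a per-modality feature matrix
#'
#' Converts one modality of a cohort into a subjects x features matrix with
#' per-column provenance: clinical gives the four questionnaire sum scores;
#' cortisol gives the single log-AUC release feature (subjects with
#' incomplete profiles are dropped with a warning); gm/wm give masked voxel
#' values under the chosen region policy (intersection mask of all subjects'
#' images, then ROI restriction).
#'
#' @param cohort A `wave_cohort`.
#' @param modality One of `"clinical"`, `"cortisol"`, `"gm"`, `"wm"`.
#' @param roi_policy Region policy for imaging modalities; defaults to
#'   `"gm_rois"` for gm and `"wm_all"` for wm. `"whole_brain"` drops the GM
#'   region restriction.
#' @param threshold Intersection-mask threshold, see
#'   [build_intersection_mask()].
#' @param n_samples Samples per complete cortisol profile.
#' @return An object of class `modality_features`: list with `modality`, `x`
#'   (numeric matrix, rownames = subject ids), `meta` (tibble `column`,
#'   `name`, `voxel`, `region`, `side`) and `subject_ids`.
#' @export
assemble_features <- function(cohort,
                              modality = c("clinical", "cortisol", "gm", "wm"),
                              roi_policy = NULL, threshold = 0, n_samples = 6) {
  modality <- match.arg(modality)
  subj <- cohort$subjects
  if (modality == "clinical") {
    x <- as.matrix(subj[, c("pswq", "bdi", "ius12", "stait")])
    rownames(x) <- subj$subject_id
    meta <- tibble::tibble(column = 1:4,
                           name = c("PSWQ", "BDI", "IUS-12", "STAI-T"),
                           voxel = NA_integer_,
                           region = c("PSWQ", "BDI", "IUS-12", "STAI-T"),
                           side = NA_character_)
    return(new_modality_features("clinical", x, meta, subj$subject_id))
  }
  if (modality == "cortisol") {
    scr <- screen_profiles(cohort$cortisol, n_samples = n_samples)
    if (length(scr$excluded_ids) > 0) {
      rlang::warn(sprintf("dropping %d subject(s) with incomplete cortisol profiles: %s",
                          length(scr$excluded_ids),
                          paste(scr$excluded_ids, collapse = ", ")))
    }
    keep <- subj$subject_id[subj$subject_id %in% scr$features$subject_id]
    assert_that(length(keep) > 0, "no usable cortisol profiles",
                class = "waveclass_empty")
    f <- scr$features[match(keep, scr$features$subject_id), ]
    x <- matrix(f$log_auc, ncol = 1, dimnames = list(keep, "log_auc"))
    meta <- tibble::tibble(column = 1L, name = "log_auc", voxel = NA_integer_,
                           region = "log_auc", side = NA_character_)
    return(new_modality_features("cortisol", x, meta, keep))
  }
  imgs <- cohort[[modality]]
  assert_that(!is.null(imgs) && length(imgs) > 0,
              sprintf("cohort has no %s images", modality),
              class = "waveclass_empty")
  roi_policy <- roi_policy %||% if (modality == "gm") "gm_rois" else "wm_all"
  mask <- build_intersection_mask(imgs, threshold = threshold)
  sel <- select_roi_voxels(mask, cohort$atlas, roi_policy)
  ids <- subj$subject_id[subj$subject_id %in% names(imgs)]
  m <- vapply(ids, function(id) imgs[[id]][sel$voxel], numeric(nrow(sel)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, ids))
  x <- t(m)
  rownames(x) <- ids
  meta <- tibble::tibble(column = seq_len(nrow(sel)),
                         name = sprintf("vox%06d", sel$voxel),
                         voxel = sel$voxel, region = sel$region,
                         side = sel$side)
  new_modality_features(modality, x, meta, ids)
}

new_modality_features <- function(modality, x, meta, subject_ids) {
  assert_that(!anyNA(x), "feature matrix contains missing values")
  assert_that(ncol(x) > 0, "feature matrix has no columns",
              class = "waveclass_empty")
  structure(list(modality = modality, x = x, meta = meta,
                 subject_ids = subject_ids),
            class = "modality_features")
}

#' @export
print.modality_features <- function(x, ...) {
  cat(sprintf("<modality_features: %s, %d subjects x %d features>\n",
              x$modality, nrow(x$x), ncol(x$x)))
  invisible(x)
}

# Restrict a modality_features object to (ordered) subject ids.
restrict_features <- function(features, ids) {
  missing <- setdiff(ids, features$subject_ids)
  assert_that(length(missing) == 0,
              sprintf("modality '%s' lacks subjects: %s", features$modality,
                      paste(missing, collapse = ", ")),
              class = "waveclass_mismatch")
  x <- features$x[match(ids, features$subject_ids), , drop = FALSE]
  new_modality_features(features$modality, x, features$meta, ids)
}

#' Assemble aligned feature matrices for all modalities
#'
#' Builds the four modality feature matrices for a cohort, excludes subjects
#' with incomplete cortisol profiles from every modality (ensemble fusion
#' requires data in all modalities for all subjects), and aligns all
#' matrices to one subject ordering.
#'
#' @inheritParams assemble_features
#' @param gm_roi_policy Region policy for the GM modality.
#' @param modalities Which modalities to assemble.
#' @return Named list of `modality_features`, all with identical
#'   `subject_ids`.
#' @export
multimodal_features <- function(cohort,
                                modalities = c("clinical", "cortisol", "gm", "wm"),
                                gm_roi_policy = "gm_rois", threshold = 0,
                                n_samples = 6) {
  feats <- lapply(modalities, function(m) {
    pol <- if (m == "gm") gm_roi_policy else NULL
    suppressWarnings(assemble_features(cohort, m, roi_policy = pol,
                                       threshold = threshold,
                                       n_samples = n_samples))
  })
  names(feats) <- modalities
  common <- Reduce(intersect, lapply(feats, function(f) f$subject_ids))
  common <- cohort$subjects$subject_id[cohort$subjects$subject_id %in% common]
  lapply(feats, restrict_features, ids = common)
}
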