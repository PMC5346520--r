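#' Write a cohort to disk
#'
#' Persists a simulated (or loaded) cohort as plain tabular files plus
#' NIfTI-1 images: `subjects.tsv`, `cortisol.tsv` (long format), per-subject
#' `gm/<id>_gm.nii.gz` and `wm/<id>_wm.nii.gz`, `atlas.nii.gz`,
#' `wm_mask.nii.gz`, `brain_mask.nii.gz`, `atlas_table.tsv` and a
#' `manifest.json` recording the seed, grid and file list. The dataset
#' round-trips losslessly through [read_cohort()], and regenerating with the
#' same config and seed yields byte-identical TSVs.
#'
#' @param cohort A `wave_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(dir), sprintf("cannot create directory '%s'", dir),
              class = "waveclass_io")
  files <- list()
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"), na = "NA")
  files$subjects <- "subjects.tsv"
  if (!is.null(cohort$cortisol)) {
    readr::write_tsv(cohort$cortisol, file.path(dir, "cortisol.tsv"))
    files$cortisol <- "cortisol.tsv"
  }
  vox <- cohort$grid$voxel_size_mm
  write_img <- function(arr, path, integer = FALSE) {
    img <- RNifti::asNifti(if (integer) array(as.integer(arr), dim = dim(arr))
                           else arr)
    RNifti::pixdim(img) <- rep(vox, 3)
    RNifti::writeNifti(img, path)
  }
  for (tissue in c("gm", "wm")) {
    if (is.null(cohort[[tissue]])) next
    tdir <- file.path(dir, tissue)
    dir.create(tdir, showWarnings = FALSE)
    rel <- character(0)
    for (id in names(cohort[[tissue]])) {
      f <- file.path(tissue, sprintf("%s_%s.nii.gz", id, tissue))
      write_img(cohort[[tissue]][[id]], file.path(dir, f))
      rel[id] <- f
    }
    files[[tissue]] <- as.list(rel)
  }
  if (!is.null(cohort$atlas)) {
    write_img(cohort$atlas$labels, file.path(dir, "atlas.nii.gz"), integer = TRUE)
    write_img(cohort$atlas$wm_mask, file.path(dir, "wm_mask.nii.gz"), integer = TRUE)
    write_img(cohort$atlas$brain_mask, file.path(dir, "brain_mask.nii.gz"),
              integer = TRUE)
    readr::write_tsv(cohort$atlas$table, file.path(dir, "atlas_table.tsv"))
    files$atlas <- "atlas.nii.gz"
    files$wm_mask <- "wm_mask.nii.gz"
    files$brain_mask <- "brain_mask.nii.gz"
    files$atlas_table <- "atlas_table.tsv"
  }
  manifest <- list(
    format = "waveclass-cohort-1",
    seed = cohort$config$seed %||% NA,
    grid = list(shape = cohort$grid$shape, voxel_size_mm = vox),
    modalities = cohort$config$modalities %||%
      c("clinical", intersect(c("cortisol", "gm", "wm"), names(cohort))),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a cohort from disk
#'
#' Reads a dataset written by [write_cohort()], validating that all
#' referenced files exist, that group labels are known, and that every image
#' shares one grid (dimensions and voxel size).
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `wave_cohort`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  assert_that(file.exists(mpath),
              sprintf("no manifest.json in '%s'", dir), class = "waveclass_io")
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  need <- function(rel) {
    p <- file.path(dir, rel)
    assert_that(file.exists(p), sprintf("missing file '%s'", p),
                class = "waveclass_io")
    p
  }
  subjects <- readr::read_tsv(need(manifest$files$subjects),
                              show_col_types = FALSE, progress = FALSE)
  bad <- which(!subjects$group %in% c("HC", "GAD", "MD"))
  assert_that(length(bad) == 0,
              sprintf("unknown group label in subjects.tsv row %d: '%s'",
                      bad[1], subjects$group[bad[1]]),
              class = "waveclass_validation")
  subjects$group <- factor(subjects$group, levels = c("HC", "GAD", "MD"))
  subjects$subject_id <- as.character(subjects$subject_id)

  cohort <- list(subjects = tibble::as_tibble(subjects))
  grid_ref <- list(shape = as.integer(unlist(manifest$grid$shape)),
                   voxel_size_mm = as.numeric(manifest$grid$voxel_size_mm))

  read_img <- function(rel) {
    img <- RNifti::readNifti(need(rel))
    pd <- RNifti::pixdim(img)[1:3]
    assert_that(identical(as.integer(dim(img)), grid_ref$shape) &&
                  all(abs(pd - grid_ref$voxel_size_mm) < 1e-6),
                sprintf("image '%s' is not on the manifest grid", rel),
                class = "waveclass_grid")
    array(as.numeric(img), dim = dim(img))
  }

  if (!is.null(manifest$files$cortisol)) {
    cohort$cortisol <- readr::read_tsv(need(manifest$files$cortisol),
                                       show_col_types = FALSE, progress = FALSE)
  }
  for (tissue in c("gm", "wm")) {
    rels <- manifest$files[[tissue]]
    if (is.null(rels)) next
    imgs <- lapply(rels, read_img)
    names(imgs) <- names(rels)
    cohort[[tissue]] <- imgs
  }
  if (!is.null(manifest$files$atlas)) {
    labels <- read_img(manifest$files$atlas)
    table <- readr::read_tsv(need(manifest$files$atlas_table),
                             show_col_types = FALSE, progress = FALSE)
    wm_mask <- read_img(manifest$files$wm_mask) > 0
    brain_mask <- read_img(manifest$files$brain_mask) > 0
    cohort$atlas <- structure(
      list(labels = array(as.integer(labels), dim = dim(labels)),
           table = tibble::as_tibble(table), wm_mask = wm_mask,
           brain_mask = brain_mask, grid = grid_ref),
      class = "roi_atlas")
  }
  cohort$grid <- grid_ref
  cohort$config <- list(seed = manifest$seed, modalities = manifest$modalities)
  structure(cohort, class = "wave_cohort")
}
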