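#' Region names of the synthetic atlas
#'
#' The 15 bilateral regions (30 region x side parcels) of the synthetic
#' parcellation: frontal and orbitofrontal gyri, anterior cingulate,
#' amygdala, hippocampus, putamen, nucleus caudate and thalamus -- the
#' regions commonly implicated in anxiety and depressive disorders and used
#' as the GM region-of-interest mask.
#'
#' @return Character vector of 15 region names.
#' @export
atlas_region_names <- function() {
  c("Superior frontal gyrus",
    "Middle frontal gyrus",
    "Inferior frontal gyrus, pars triangularis",
    "Inferior frontal gyrus, pars opercularis",
    "Superior medial frontal gyrus",
    "Superior frontal gyrus, orbital",
    "Middle frontal gyrus, orbital",
    "Inferior frontal gyrus, orbital",
    "Medial frontal gyrus, orbital",
    "Anterior cingulate gyrus",
    "Amygdala",
    "Hippocampus",
    "Putamen",
    "Nucleus caudate",
    "Thalamus")
}

# Box extents (voxels) per region; frontal gyri are larger, subcortical
# structures smaller, loosely mirroring real parcel volumes.
atlas_box_sizes <- function() {
  tibble::tribble(
    ~region,                                      ~dx, ~dy, ~dz,
    "Superior frontal gyrus",                      4,   4,   4,
    "Middle frontal gyrus",                        4,   4,   4,
    "Inferior frontal gyrus, pars triangularis",   3,   4,   3,
    "Inferior frontal gyrus, pars opercularis",    3,   3,   3,
    "Superior medial frontal gyrus",               4,   4,   3,
    "Superior frontal gyrus, orbital",             3,   3,   3,
    "Middle frontal gyrus, orbital",               3,   3,   3,
    "Inferior frontal gyrus, orbital",             3,   3,   3,
    "Medial frontal gyrus, orbital",               3,   3,   3,
    "Anterior cingulate gyrus",                    3,   4,   3,
    "Amygdala",                                    2,   3,   2,
    "Hippocampus",                                 3,   3,   3,
    "Putamen",                                     3,   3,   3,
    "Nucleus caudate",                             3,   3,   3,
    "Thalamus",                                    3,   3,   3
  )
}

#' Build the synthetic ROI atlas
#'
#' Places 30 axis-aligned boxes (15 regions x left/right, mirrored about the
#' mid-sagittal plane) plus one white-matter compartment on a shared voxel
#' grid. Voxels inside the brain envelope but outside all boxes are
#' unlabelled gray matter, so whole-brain feature selection is a strict
#' superset of the ROI selection. A user-supplied integer-labelled NIfTI
#' atlas on the same grid is accepted as a drop-in anywhere a `roi_atlas` is
#' consumed.
#'
#' @param grid_shape Integer length-3 voxel counts (default 40 x 48 x 40).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return An object of class `roi_atlas`: list with `labels` (3D integer
#'   array, 0 = unlabelled), `table` (tibble `label`, `region`, `side`,
#'   `n_voxels`), `wm_mask` and `brain_mask` (3D logical arrays), `grid`
#'   (list of `shape` and `voxel_size_mm`).
#' @export
build_synthetic_atlas <- function(grid_shape = c(40L, 48L, 40L),
                                  voxel_size_mm = 3.0) {
  grid_shape <- as.integer(grid_shape)
  assert_that(all(grid_shape >= c(32L, 40L, 32L)),
              "grid_shape too small for the synthetic atlas (min 32 x 40 x 32)")
  d <- grid_shape
  labels <- array(0L, dim = d)

  sizes <- atlas_box_sizes()
  # Slot layout in the y-z plane, scaled to the grid.
  yslots <- round(seq(4, d[2] - 9, length.out = 5))
  zslots <- round(seq(5, round(d[3] * 0.72) - 5, length.out = 3))
  x_left <- 4L
  rows <- list()
  for (r in seq_len(nrow(sizes))) {
    dx <- sizes$dx[r]; dy <- sizes$dy[r]; dz <- sizes$dz[r]
    y0 <- yslots[((r - 1) %% 5) + 1]
    z0 <- zslots[((r - 1) %/% 5) + 1]
    for (side in c("L", "R")) {
      x0 <- if (side == "L") x_left else d[1] - x_left - dx + 1L
      lab <- length(rows) + 1L
      labels[x0:(x0 + dx - 1), y0:(y0 + dy - 1), z0:(z0 + dz - 1)] <- lab
      rows[[lab]] <- tibble::tibble(label = lab, region = sizes$region[r],
                                    side = side, n_voxels = dx * dy * dz)
    }
  }
  table <- dplyr::bind_rows(rows)
  assert_that(sum(labels > 0) == sum(table$n_voxels),
              "internal atlas layout error: region boxes overlap")

  # White-matter compartment: a central box above the GM slots.
  wm_mask <- array(FALSE, dim = d)
  wx <- round(d[1] / 2) + (-5:4)
  wy <- round(d[2] / 2) + (-6:5)
  wz <- round(d[3] * 0.8) + (0:5)
  wz <- wz[wz <= d[3]]
  wm_mask[wx, wy, wz] <- TRUE
  assert_that(!any(labels[wm_mask] > 0),
              "internal atlas layout error: WM compartment overlaps a GM box")

  # Brain envelope: everything except a margin; GM = envelope minus WM box.
  brain_mask <- array(FALSE, dim = d)
  brain_mask[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE

  structure(list(labels = labels, table = table, wm_mask = wm_mask,
                 brain_mask = brain_mask,
                 grid = list(shape = d, voxel_size_mm = voxel_size_mm)),
            class = "roi_atlas")
}
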