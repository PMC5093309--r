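#' Parameters for EYFP cell detection and watershed splitting
#'
#' Defaults are tied to the expected cell scale. Because the robust
#' detection threshold sits just above the background distribution, the
#' effective segment boundary is where the DoG response crosses zero,
#' and that zero-crossing sits roughly sigma_small outside the true
#' cell surface: a small sigma_small (cell_radius / 3) keeps the
#' recovered volume faithful, while a generous sigma_large
#' (3 cell_radius) keeps the interior of merged multi-cell clones
#' band-passed positive. The minimum component size is the voxel volume
#' of a sphere of radius cell_radius / 2, and the watershed seed
#' threshold is cell_radius / 2.
#'
#' @param sigma_small small DoG scale, um.
#' @param sigma_large large DoG scale, um; must exceed `sigma_small`.
#' @param min_cell_size minimum component size in voxels.
#' @param watershed_seed_threshold distance-transform threshold (um) used
#'   to extract watershed seed markers.
#' @return a `detection_params` object.
#' @export
detection_params <- function(sigma_small, sigma_large, min_cell_size,
                             watershed_seed_threshold) {
  if (!(sigma_small > 0 && sigma_small < sigma_large))
    stop(sprintf("need 0 < sigma_small < sigma_large (got %g, %g)",
                 sigma_small, sigma_large))
  min_cell_size <- as.integer(min_cell_size)
  if (min_cell_size < 1L) stop("min_cell_size must be >= 1")
  structure(list(sigma_small = sigma_small, sigma_large = sigma_large,
                 min_cell_size = min_cell_size,
                 watershed_seed_threshold = watershed_seed_threshold),
            class = "detection_params")
}

#' Default detection parameters from the cell scale
#'
#' @param cell_radius expected cell radius, um.
#' @param spacing voxel spacing (dx, dy, dz), um; used to express the
#'   minimum size in voxels.
#' @return a `detection_params` object.
#' @export
default_detection_params <- function(cell_radius, spacing) {
  voxvol <- prod(spacing)
  minsize <- max(1L, round((4 / 3) * pi * (cell_radius / 2)^3 / voxvol))
  detection_params(sigma_small = cell_radius / 3,
                   sigma_large = 3 * cell_radius,
                   min_cell_size = minsize,
                   watershed_seed_threshold = cell_radius / 2)
}

#' Detection parameters for elongated (spindle-shaped) cells
#'
#' Basal myoepithelial cells are elongated along the duct axis and thin
#' transversally, so the spherical `min_cell_size` default over-prunes
#' partially detected spindles. Here the minimum size is the voxel
#' volume of a half-linear-scale ellipsoid with semi-axes
#' `(along * cell_radius, trans * cell_radius, trans * cell_radius)`.
#' The DoG scales and the watershed seed threshold keep their
#' [default_detection_params()] values.
#'
#' @param cell_radius expected (spherical-equivalent) cell radius, um.
#' @param spacing voxel spacing, um.
#' @param along,trans semi-axis factors of the spindle relative to
#'   `cell_radius` (defaults 2.5 and 0.5, an axis ratio of 5).
#' @return a `detection_params` object.
#' @export
elongated_detection_params <- function(cell_radius, spacing,
                                       along = 2.5, trans = 0.5) {
  if (!(along > 0 && trans > 0)) stop("along and trans must be > 0")
  voxvol <- prod(spacing)
  minsize <- max(1L, round((4 / 3) * pi * (along * cell_radius / 2) *
                           (trans * cell_radius / 2)^2 / voxvol))
  detection_params(sigma_small = cell_radius / 3,
                   sigma_large = 3 * cell_radius,
                   min_cell_size = minsize,
                   watershed_seed_threshold = cell_radius / 2)
}

# build a cell_segments object from a labeled array (labels renumbered
# consecutively, sorted by first voxel for determinism)
segments_from_labels <- function(labels, spacing) {
  ids <- sort(unique(labels[labels > 0L]))
  tab <- vector("list", length(ids))
  vox <- vector("list", length(ids))
  d <- dim(labels)
  for (i in seq_along(ids)) {
    lin <- which(labels == ids[i])
    idx <- arrayInd(lin, d)
    cen <- colMeans(voxel_centres_um(idx, spacing))
    tab[[i]] <- data.frame(id = i, size_voxels = length(lin),
                           cx = cen[1], cy = cen[2], cz = cen[3])
    vox[[i]] <- lin
  }
  relab <- array(0L, d)
  for (i in seq_along(ids)) relab[vox[[i]]] <- i
  structure(list(
    table = if (length(tab)) do.call(rbind, tab) else
      data.frame(id = integer(), size_voxels = integer(),
                 cx = numeric(), cy = numeric(), cz = numeric()),
    voxels = vox, labels = relab, spacing = spacing),
    class = "cell_segments")
}

#' @export
print.cell_segments <- function(x, ...) {
  cat(sprintf("<cell_segments> %d segments, %d voxels total\n",
              nrow(x$table), sum(x$table$size_voxels)))
  invisible(x)
}

#' Detect EYFP-positive cells inside the duct
#'
#' Difference-of-Gaussians filtering of the full-resolution EYFP channel,
#' robust median + 3 MAD thresholding of the filtered intensities,
#' 26-connected component extraction, removal of components below
#' `min_cell_size`, and clipping to the duct mask (components left empty
#' by the clipping are dropped): only EYFP+ cells inside the detected
#' duct are taken into account.
#'
#' @param eyfp a `voxel_grid` holding the EYFP channel.
#' @param duct a `duct_model` on the same grid.
#' @param params a `detection_params` object.
#' @param dog optional precomputed `dog_filter(eyfp, params)` result, to
#'   avoid refiltering.
#' @return a `cell_segments` object (table, per-segment voxel indices,
#'   labeled array) with the threshold used in attribute
#'   `"dog_threshold"`.
#' @export
detect_eyfp_cells <- function(eyfp, duct, params, dog = NULL) {
  stopifnot(inherits(eyfp, "voxel_grid"), inherits(duct, "duct_model"))
  if (is.null(dog)) dog <- dog_filter(eyfp, params)
  thr <- robust_threshold(as.numeric(dog$data))
  mask <- dog$data > thr
  labels <- label_components(mask, 26L)
  if (any(labels > 0L)) {
    sizes <- tabulate(labels)
    keep <- which(sizes >= params$min_cell_size)
    labels[!(labels %in% keep)] <- 0L
    labels[!duct$duct_mask] <- 0L
  }
  segs <- segments_from_labels(labels, eyfp$spacing)
  attr(segs, "dog_threshold") <- thr
  segs
}

#' Split merged cells by seeded watershed
#'
#' Computes the Euclidean distance transform of the binary cell mask in
#' physical units, takes the connected components of
#' {distance > watershed_seed_threshold} as seed markers, and floods the
#' negated distance restricted to the mask. The output labels partition
#' the input mask exactly. If the threshold exceeds the maximum distance
#' of some input component, that component falls back to a single seed at
#' its distance maximum (with a warning).
#'
#' @param cell_mask logical 3D array.
#' @param params a `detection_params` object.
#' @param spacing voxel spacing (dx, dy, dz) in um.
#' @return integer 3D array of labels partitioning `cell_mask`.
#' @export
watershed_split <- function(cell_mask, params, spacing) {
  stopifnot(is.array(cell_mask), length(dim(cell_mask)) == 3L)
  cell_mask <- cell_mask > 0
  if (!any(cell_mask)) return(array(0L, dim(cell_mask)))
  dist <- distance_transform(cell_mask, spacing)
  seeds <- label_components(dist > params$watershed_seed_threshold, 26L)
  comp <- label_components(cell_mask, 26L)
  ncomp <- max(comp)
  seeded <- unique(comp[seeds > 0L])
  missing <- setdiff(seq_len(ncomp), seeded)
  if (length(missing) > 0) {
    warning(sprintf(
      "watershed seed threshold %g um exceeds the maximum distance of %d component(s); using one seed per such component",
      params$watershed_seed_threshold, length(missing)))
    nextlab <- max(seeds)
    for (m in missing) {
      lin <- which(comp == m)
      nextlab <- nextlab + 1L
      seeds[lin[which.max(dist[lin])]] <- nextlab
    }
  }
  .cpp_watershed3(-dist, seeds, cell_mask, dim(cell_mask), 26L)
}

#' Seed count as a function of the watershed seed threshold
#'
#' The watershed seed threshold trades over- against under-splitting:
#' too low and touching cells share one seed, too high and components
#' lose their seed entirely (triggering the one-seed fallback). This
#' diagnostic profiles the number of seed components over a threshold
#' range so the choice can be inspected, mirroring the manual selection
#' the method otherwise requires.
#'
#' @param cell_mask logical 3D array (the thresholded EYFP segmentation).
#' @param spacing voxel spacing (dx, dy, dz) in um.
#' @param thresholds distance thresholds (um) to profile; default 20
#'   steps from 0 to the maximum interior distance.
#' @return data.frame(threshold, n_seeds).
#' @export
seed_count_profile <- function(cell_mask, spacing, thresholds = NULL) {
  stopifnot(is.array(cell_mask), length(dim(cell_mask)) == 3L)
  cell_mask <- cell_mask > 0
  if (!any(cell_mask))
    return(data.frame(threshold = numeric(), n_seeds = integer()))
  dist <- distance_transform(cell_mask, spacing)
  if (is.null(thresholds))
    thresholds <- seq(0, max(dist), length.out = 20)
  n <- vapply(thresholds, function(t)
    max(label_components(dist > t, 26L)), integer(1))
  data.frame(threshold = thresholds, n_seeds = n)
}
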