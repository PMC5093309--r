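#' Separable 3D Gaussian filter in physical units
#'
#' Smooths a voxel grid with an axis-aligned Gaussian whose standard
#' deviation is given in micrometres; each axis uses sigma divided by that
#' axis' voxel spacing, so anisotropic stacks are handled correctly.
#' Boundaries are reflected.
#'
#' @param grid a `voxel_grid`.
#' @param sigma_um Gaussian sd in um: either one value (isotropic in
#'   physical space) or three values (x, y, z).
#' @return a `voxel_grid` of the same shape.
#' @export
gaussian_blur <- function(grid, sigma_um) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(sigma_um) == 1L) sigma_um <- rep(sigma_um, 3L)
  if (length(sigma_um) == 2L) sigma_um <- c(sigma_um[1], sigma_um[1], sigma_um[2])
  if (any(sigma_um < 0)) stop("sigma must be nonnegative")
  sig_vox <- sigma_um / grid$spacing
  out <- .cpp_gaussian_blur3(as.numeric(grid$data), dim(grid$data),
                             as.numeric(sig_vox))
  voxel_grid(array(out, dim(grid$data)), grid$spacing)
}

#' Difference-of-Gaussians band-pass filter
#'
#' The blob-detection filter applied to the full-resolution EYFP channel:
#' the grid smoothed at the small scale minus the grid smoothed at the
#' large scale. Scales are physical (um) so axial anisotropy is absorbed
#' by the voxel spacing.
#'
#' @param grid a `voxel_grid`.
#' @param params a `detection_params` object (or any list with
#'   `sigma_small` and `sigma_large` in um).
#' @return a `voxel_grid` of band-pass responses (mean approximately zero).
#' @export
dog_filter <- function(grid, params) {
  stopifnot(inherits(grid, "voxel_grid"))
  ss <- params$sigma_small
  sl <- params$sigma_large
  if (!is.numeric(ss) || !is.numeric(sl) || ss <= 0 || ss >= sl)
    stop(sprintf("need 0 < sigma_small < sigma_large (got %s, %s)",
                 format(ss), format(sl)))
  a <- gaussian_blur(grid, ss)
  b <- gaussian_blur(grid, sl)
  voxel_grid(a$data - b$data, grid$spacing)
}

# shift a 3D array by (sx, sy, sz) with edge replication
shift_arr3 <- function(a, s) {
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1]) - s[1], 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) - s[2], 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3]) - s[3], 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

# binary dilation / erosion with the 3x3x3 (26-neighbourhood) structuring
# element; edge-replicated boundary
morph_dilate3 <- function(mask) {
  out <- mask
  for (sz in -1:1) for (sy in -1:1) for (sx in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    out <- out | shift_arr3(mask, c(sx, sy, sz))
  }
  out
}

morph_erode3 <- function(mask) {
  out <- mask
  for (sz in -1:1) for (sy in -1:1) for (sx in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    out <- out & shift_arr3(mask, c(sx, sy, sz))
  }
  out
}

# one closing pass (seals decimation seams after block-replication upsampling)
morph_close3 <- function(mask) morph_erode3(morph_dilate3(mask))

#' Label connected components of a 3D binary mask
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (default) or 6.
#' @return integer 3D array of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  .cpp_label3(as.logical(mask), dim(mask), as.integer(connectivity))
}

#' Anisotropic Euclidean distance transform
#'
#' Distance (um) from each foreground voxel to the nearest background
#' voxel, honouring the physical voxel spacing.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing (dx, dy, dz) in um.
#' @return numeric 3D array of distances, 0 on background.
#' @export
distance_transform <- function(mask, spacing) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  .cpp_edt3(as.logical(mask), dim(mask), as.numeric(spacing))
}
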