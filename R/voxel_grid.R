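#' Voxel grid with physical spacing
#'
#' A 3D scalar intensity grid together with its voxel spacing in micrometres.
#' The array is column-major with dimensions (nx, ny, nz); z is the slowest
#' axis. Voxel indices are 0-based in physical terms: the centre of voxel
#' (i, j, k) lies at ((i + 0.5) dx, (j + 0.5) dy, (k + 0.5) dz).
#'
#' @param data numeric 3D array of finite intensities.
#' @param spacing numeric length-3 vector of voxel spacing (dx, dy, dz) in um.
#' @return an object of class `voxel_grid` with elements `data` and `spacing`.
#' @export
voxel_grid <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("`data` must contain only finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (dx, dy, dz) in um")
  structure(list(data = data, spacing = spacing), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %.3g/%.3g/%.3g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

as_voxel_grid <- function(x, spacing) {
  if (inherits(x, "voxel_grid")) return(x)
  voxel_grid(x, spacing)
}

#' Multi-channel image stack
#'
#' Co-registered voxel grids, one per named channel, sharing a common
#' spacing. The pipeline expects channels named "EYFP", "K8" and "SMA";
#' additional channels (e.g. "DAPI") are carried through untouched.
#'
#' @param channels named list of 3D arrays with identical dimensions.
#' @param spacing voxel spacing (dx, dy, dz) in um.
#' @return an object of class `multichannel_stack`.
#' @export
multichannel_stack <- function(channels, spacing) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("`channels` must be a fully named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values")
  structure(list(channels = channels, spacing = spacing),
            class = "multichannel_stack")
}

#' @export
print.multichannel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_stack> %s | %d x %d x %d voxels, spacing %.3g/%.3g/%.3g um\n",
              paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Extract one channel of a stack as a voxel grid
#'
#' @param stack a `multichannel_stack`.
#' @param name channel name.
#' @return a `voxel_grid`.
#' @export
stack_channel <- function(stack, name) {
  stopifnot(inherits(stack, "multichannel_stack"))
  if (!name %in% names(stack$channels))
    stop(sprintf("channel '%s' not present (found: %s)", name,
                 paste(names(stack$channels), collapse = ", ")))
  voxel_grid(stack$channels[[name]], stack$spacing)
}

# physical centre coordinates (um) of voxel array indices (1-based R indices)
voxel_centres_um <- function(idx, spacing) {
  sweep(idx - 0.5, 2, spacing, `*`)
}
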