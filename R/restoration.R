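#' Restoration parameters (denoise + deblur)
#'
#' Pre-processing used by the basal-clone analysis variant, where deep
#' imaging gives a poorer signal-to-noise ratio: a variance-stabilized
#' wavelet denoising step followed by Richardson-Lucy deblurring with a
#' Gaussian PSF.
#'
#' @param denoise_strength nonnegative soft-threshold multiplier in units
#'   of the robustly estimated noise scale (0 disables denoising).
#' @param psf_sigma Gaussian PSF sd in um, length 2 (lateral, axial).
#' @param deblur_iterations positive integer Richardson-Lucy iterations.
#' @param denoise_levels wavelet decomposition depth for the denoiser.
#' @return a `restoration_params` object.
#' @export
restoration_params <- function(denoise_strength = 2, psf_sigma = c(0.6, 1.8),
                               deblur_iterations = 10L, denoise_levels = 2L) {
  if (denoise_strength < 0) stop("denoise_strength must be >= 0")
  deblur_iterations <- as.integer(deblur_iterations)
  if (deblur_iterations < 1L) stop("deblur_iterations must be >= 1")
  if (length(psf_sigma) != 2L || any(psf_sigma < 0))
    stop("psf_sigma must be (lateral, axial), both >= 0")
  structure(list(denoise_strength = denoise_strength,
                 psf_sigma = as.numeric(psf_sigma),
                 deblur_iterations = deblur_iterations,
                 denoise_levels = as.integer(denoise_levels)),
            class = "restoration_params")
}

# multi-level 3D Haar soft-threshold shrinkage; returns an array of the
# same dims (pads to even internally, crops after the inverse transform)
haar_shrink_rec <- function(a, levels, strength) {
  d0 <- dim(a)
  a <- pad_to_multiple(a, c(2, 2, 2))
  w <- haar3_fwd1(a)
  h <- dim(w) %/% 2L
  hhh <- w[(h[1] + 1):(2 * h[1]), (h[2] + 1):(2 * h[2]),
           (h[3] + 1):(2 * h[3]), drop = FALSE]
  thr <- strength * stats::median(abs(hhh)) / 0.6745
  if (thr > 0) {
    detm <- array(TRUE, dim(w))
    detm[seq_len(h[1]), seq_len(h[2]), seq_len(h[3])] <- FALSE
    dv <- w[detm]
    w[detm] <- sign(dv) * pmax(abs(dv) - thr, 0)
  }
  if (levels > 1L && all(h >= 2L)) {
    w[seq_len(h[1]), seq_len(h[2]), seq_len(h[3])] <-
      haar_shrink_rec(w[seq_len(h[1]), seq_len(h[2]), seq_len(h[3]),
                        drop = FALSE], levels - 1L, strength)
  }
  out <- haar3_inv1(w)
  out[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
}

#' Denoise a stack by variance-stabilized wavelet shrinkage
#'
#' Applies the Anscombe variance-stabilizing transform, soft-thresholds
#' the detail coefficients of a multi-level orthonormal 3D Haar transform
#' at `denoise_strength` times the robust noise scale (MAD of the finest
#' diagonal sub-band / 0.6745), inverts the transform and the VST, and
#' clamps to nonnegative intensities. `denoise_strength = 0` returns the
#' input unchanged.
#'
#' @param grid a `voxel_grid`.
#' @param params a `restoration_params` object.
#' @return a denoised `voxel_grid` of the same shape and spacing.
#' @export
denoise_stack <- function(grid, params = restoration_params()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (params$denoise_strength == 0) return(grid)
  v <- 2 * sqrt(pmax(grid$data, 0) + 3 / 8)
  v <- haar_shrink_rec(v, params$denoise_levels, params$denoise_strength)
  out <- pmax((v / 2)^2 - 3 / 8, 0)
  voxel_grid(array(out, dim(grid$data)), grid$spacing)
}

#' Deblur a stack by Richardson-Lucy deconvolution
#'
#' Iterative Richardson-Lucy deconvolution with an anisotropic Gaussian
#' PSF (sd `psf_sigma` um, lateral/axial). Total intensity is
#' renormalized to the input's after each iteration, so flux is conserved
#' by construction.
#'
#' @param grid a `voxel_grid`.
#' @param params a `restoration_params` object; `psf_sigma` must be
#'   positive.
#' @return a deblurred, nonnegative `voxel_grid` of the same shape.
#' @export
deblur_stack <- function(grid, params = restoration_params()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (any(params$psf_sigma <= 0)) stop("psf_sigma must be positive")
  sigma <- c(params$psf_sigma[1], params$psf_sigma[1], params$psf_sigma[2])
  y <- pmax(grid$data, 0)
  total <- sum(y)
  if (total == 0) return(voxel_grid(y, grid$spacing))
  eps <- 1e-12 * max(y)
  x <- y
  for (it in seq_len(params$deblur_iterations)) {
    est <- gaussian_blur(voxel_grid(x, grid$spacing), sigma)$data
    ratio <- y / pmax(est, eps)
    x <- x * gaussian_blur(voxel_grid(ratio, grid$spacing), sigma)$data
    if (!all(is.finite(x)))
      stop("non-finite values during deconvolution; reduce deblur_iterations")
    x <- x * (total / sum(x))
  }
  voxel_grid(pmax(x, 0), grid$spacing)
}
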