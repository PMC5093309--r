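#' Parameters for duct segmentation and significant-voxel detection
#'
#' @param coarse_level lateral decimation level of the multiresolution
#'   transform used to detect the duct (default 3, i.e. 8x8 lateral
#'   pooling).
#' @param fdr_q false discovery rate for plane-wise significant-voxel
#'   detection, in (0, 1).
#' @param coarse_level_z optional z decimation level (default: derived
#'   from the spacing anisotropy, see [multiresolution_coarse()]).
#' @param closing apply one 26-neighbourhood morphological closing to the
#'   up-sampled duct mask to seal decimation seams (default TRUE).
#' @return a `wavelet_params` object.
#' @export
wavelet_params <- function(coarse_level = 3L, fdr_q = 0.05,
                           coarse_level_z = NULL, closing = TRUE) {
  coarse_level <- as.integer(coarse_level)
  if (coarse_level < 1L) stop("coarse_level must be >= 1")
  if (!is.numeric(fdr_q) || fdr_q <= 0 || fdr_q >= 1)
    stop("fdr_q must lie in (0, 1)")
  structure(list(coarse_level = coarse_level, fdr_q = fdr_q,
                 coarse_level_z = coarse_level_z, closing = isTRUE(closing)),
            class = "wavelet_params")
}

new_duct_model <- function(duct_mask, significant_mask = NULL) {
  structure(list(duct_mask = duct_mask,
                 duct_volume_voxels = sum(duct_mask),
                 significant_mask = significant_mask),
            class = "duct_model")
}

#' @export
print.duct_model <- function(x, ...) {
  cat(sprintf("<duct_model> %d duct voxels", x$duct_volume_voxels))
  if (!is.null(x$significant_mask))
    cat(sprintf(", %d significant voxels", sum(x$significant_mask)))
  cat("\n")
  invisible(x)
}

#' Segment the duct from the K8 channel
#'
#' Computes the coarse multiresolution approximation of the K8 channel,
#' thresholds it with the robust median + 3 MAD rule pooled over the whole
#' transformed stack, and up-samples the thresholded mask back to full
#' resolution by block replication (optionally followed by one
#' morphological closing). The number of true voxels of the resulting mask
#' is the duct volume measure.
#'
#' @param k8 a `voxel_grid` holding the K8 channel.
#' @param params a `wavelet_params` object.
#' @return a `duct_model` with `duct_mask` and `duct_volume_voxels`
#'   (significant_mask unset). An empty mask is a valid result and is
#'   reported with a warning.
#' @export
segment_duct <- function(k8, params = wavelet_params()) {
  stopifnot(inherits(k8, "voxel_grid"))
  coarse <- multiresolution_coarse(k8, params$coarse_level,
                                   params$coarse_level_z)
  thr <- robust_threshold(as.numeric(coarse$data))
  cmask <- coarse$data > thr
  f <- round(coarse$spacing / k8$spacing)
  mask <- upsample_block(cmask, f, dim(k8$data))
  if (params$closing && any(mask)) mask <- morph_close3(mask)
  if (!any(mask))
    warning("duct segmentation produced an empty mask")
  new_duct_model(mask)
}

#' Detect significant (cellular) voxels within the duct
#'
#' Plane by plane, the K8 image is 2D wavelet transformed and the fine
#' detail coefficients are converted to two-sided p-values under a
#' Gaussian null whose scale is estimated robustly (MAD / 0.6745) per
#' plane and sub-band. Benjamini-Hochberg FDR thresholding at level
#' `fdr_q` selects coefficients; a voxel is significant when any detail
#' coefficient covering it survives. The result is intersected with the
#' duct mask, excluding intercellular spaces and nuclei from the duct
#' interior.
#'
#' @param k8 a `voxel_grid` holding the K8 channel.
#' @param duct a `duct_model` computed on the same grid.
#' @param fdr_q FDR level in (0, 1).
#' @return logical 3D array (significant voxels, subset of the duct mask).
#' @export
detect_significant_voxels <- function(k8, duct, fdr_q = 0.05) {
  stopifnot(inherits(k8, "voxel_grid"), inherits(duct, "duct_model"))
  if (!is.numeric(fdr_q) || fdr_q <= 0 || fdr_q >= 1)
    stop("fdr_q must lie in (0, 1)")
  d <- dim(k8$data)
  sig <- array(FALSE, d)
  for (z in seq_len(d[3]))
    sig[, , z] <- plane_significant(k8$data[, , z], fdr_q)
  sig & duct$duct_mask
}

#' Attach the significant-voxel mask to a duct model
#'
#' @param duct a `duct_model`.
#' @param significant_mask logical 3D array (will be intersected with the
#'   duct mask).
#' @return the updated `duct_model`.
#' @export
set_significant_mask <- function(duct, significant_mask) {
  stopifnot(inherits(duct, "duct_model"))
  duct$significant_mask <- significant_mask & duct$duct_mask
  duct
}
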