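#' Robust median + 3 MAD threshold
#'
#' The segmentation threshold used throughout the pipeline: the median of
#' the supplied values plus three times their median absolute deviation
#' (raw MAD, no consistency constant). Applied to multiresolution
#' coefficients for duct segmentation and to difference-of-Gaussians
#' filtered intensities for cell detection.
#'
#' @param values nonempty numeric vector (NA not allowed).
#' @return a single numeric threshold, median(v) + 3 * median(|v - median(v)|).
#' @examples
#' robust_threshold(c(1, 2, 3, 4, 100))  # 6
#' @export
robust_threshold <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("`values` must be nonempty")
  if (anyNA(values))
    stop("`values` must not contain NA")
  m <- stats::median(values)
  m + 3 * stats::median(abs(values - m))
}
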