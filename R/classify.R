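#' Classification parameters for the luminal/basal call
#'
#' @param thresholds strictly increasing intensity levels used for the
#'   multi-threshold vote; default 100, 300, ..., 1500 on the 12-bit
#'   scale. For other bit depths rescale with `intensity_scale`.
#' @param sma_detectability_fraction minimum fraction of
#'   above-lowest-threshold SMA voxels in a cell's dilated neighbourhood
#'   for the local basal shell to count as detectable; cells failing this
#'   are excluded from classification.
#' @param intensity_scale multiplier applied to `thresholds` (e.g.
#'   16 for 16-bit data acquired with the same relative levels).
#' @return a `classification_params` object.
#' @export
classification_params <- function(thresholds = seq(100, 1500, by = 200),
                                  sma_detectability_fraction = 0.01,
                                  intensity_scale = 1) {
  thresholds <- as.numeric(thresholds) * intensity_scale
  if (length(thresholds) == 0L || any(diff(thresholds) <= 0))
    stop("thresholds must be a nonempty strictly increasing vector")
  if (sma_detectability_fraction < 0 || sma_detectability_fraction > 1)
    stop("sma_detectability_fraction must lie in [0, 1]")
  structure(list(thresholds = thresholds,
                 sma_detectability_fraction = sma_detectability_fraction),
            class = "classification_params")
}

#' Count K8 and SMA voxels above a threshold within a cell
#'
#' @param cell_voxels integer vector of linear voxel indices of the cell.
#' @param k8,sma 3D arrays (same grid).
#' @param t intensity threshold; counting uses strict inequality
#'   ("exceeding" the threshold).
#' @return integer vector c(n_k8, n_sma).
#' @export
count_lineage_voxels <- function(cell_voxels, k8, sma, t) {
  c(n_k8 = sum(k8[cell_voxels] > t), n_sma = sum(sma[cell_voxels] > t))
}

#' Single-threshold lineage vote
#'
#' Luminal if the K8 voxel count strictly exceeds the SMA count,
#' otherwise (including ties) basal.
#'
#' @param n_k8,n_sma nonnegative voxel counts.
#' @return "luminal" or "basal".
#' @export
vote_at_threshold <- function(n_k8, n_sma) {
  if (n_k8 < 0 || n_sma < 0) stop("counts must be >= 0")
  if (n_k8 > n_sma) "luminal" else "basal"
}

#' Is the SMA signal detectable around a cell?
#'
#' Cells lying in regions where the SMA signal is undetectable (so the
#' nested double-layer tubular structure cannot be observed) must be
#' excluded from classification. The criterion is quantitative: within a
#' one-cell-radius dilation of the cell restricted to the duct, the
#' fraction of voxels with SMA above the lowest classification threshold
#' must reach `sma_detectability_fraction`.
#'
#' @param cell_voxels linear voxel indices of the cell.
#' @param sma 3D SMA array.
#' @param duct a `duct_model`.
#' @param params a `classification_params` object.
#' @param cell_radius dilation radius, um.
#' @param spacing voxel spacing, um.
#' @return logical.
#' @export
sma_detectable <- function(cell_voxels, sma, duct, params, cell_radius,
                           spacing) {
  if (params$sma_detectability_fraction == 0) return(TRUE)
  d <- dim(sma)
  idx <- arrayInd(cell_voxels, d)
  grow <- as.integer(ceiling(cell_radius / spacing)) + 1L
  lo <- pmax(apply(idx, 2, min) - grow, 1L)
  hi <- pmin(apply(idx, 2, max) + grow, d)
  bd <- hi - lo + 1L
  # physical distance-to-cell inside the bounding box, via the distance
  # transform of the cell's complement
  cellbox <- array(FALSE, bd)
  cellbox[cbind(idx[, 1] - lo[1] + 1L, idx[, 2] - lo[2] + 1L,
                idx[, 3] - lo[3] + 1L)] <- TRUE
  dist <- .cpp_edt3(!cellbox, bd, spacing)
  nb <- which(array(dist, bd) <= cell_radius)
  bidx <- arrayInd(nb, bd)
  lin <- (bidx[, 1] + lo[1] - 1L) +
    (bidx[, 2] + lo[2] - 2L) * d[1] +
    (bidx[, 3] + lo[3] - 2L) * d[1] * d[2]
  lin <- lin[duct$duct_mask[lin]]
  if (length(lin) == 0L) return(FALSE)
  mean(sma[lin] > min(params$thresholds)) >= params$sma_detectability_fraction
}

#' Classify one cell as luminal or basal
#'
#' Multi-threshold majority vote: at each configured threshold the cell's
#' K8 and SMA voxel counts above the threshold are compared (K8 strictly
#' greater -> luminal vote, otherwise basal). The strict majority of
#' votes is the final call; an exact tie across thresholds gives
#' "unclassified". If the SMA signal is undetectable in the cell's
#' neighbourhood the cell is excluded ("unclassified" with the reason
#' recorded).
#'
#' @param cell_voxels linear voxel indices of the cell.
#' @param k8,sma 3D arrays.
#' @param params a `classification_params` object.
#' @param duct optional `duct_model`; with `cell_radius` and `spacing`
#'   enables the SMA-detectability exclusion.
#' @param cell_radius,spacing see [sma_detectable()].
#' @return a `lineage_call`: list(call, votes data.frame
#'   (threshold, n_k8, n_sma, vote), exclusion_reason).
#' @export
classify_cell <- function(cell_voxels, k8, sma, params = classification_params(),
                          duct = NULL, cell_radius = NULL, spacing = NULL) {
  votes <- data.frame(threshold = params$thresholds, n_k8 = NA_integer_,
                      n_sma = NA_integer_, vote = NA_character_)
  for (i in seq_along(params$thresholds)) {
    ns <- count_lineage_voxels(cell_voxels, k8, sma, params$thresholds[i])
    votes$n_k8[i] <- ns[1]
    votes$n_sma[i] <- ns[2]
    votes$vote[i] <- vote_at_threshold(ns[1], ns[2])
  }
  exclusion <- NULL
  if (!is.null(duct) && !is.null(cell_radius) && !is.null(spacing) &&
      !sma_detectable(cell_voxels, sma, duct, params, cell_radius, spacing)) {
    exclusion <- "SMA signal undetectable in the cell neighbourhood"
    call <- "unclassified"
  } else {
    nl <- sum(votes$vote == "luminal")
    nb <- sum(votes$vote == "basal")
    call <- if (nl > nb) "luminal" else if (nb > nl) "basal" else "unclassified"
  }
  structure(list(call = call, votes = votes, exclusion_reason = exclusion),
            class = "lineage_call")
}

#' Classify every detected cell segment
#'
#' @param segments a `cell_segments` object.
#' @param k8,sma `voxel_grid`s of the marker channels.
#' @param params a `classification_params` object.
#' @param duct optional `duct_model` enabling the SMA exclusion rule.
#' @param cell_radius dilation radius for the exclusion rule, um.
#' @return data.frame: cell_id, call, votes_luminal, votes_basal,
#'   excluded, reason.
#' @export
classify_segments <- function(segments, k8, sma,
                              params = classification_params(),
                              duct = NULL, cell_radius = NULL) {
  stopifnot(inherits(segments, "cell_segments"))
  n <- nrow(segments$table)
  out <- data.frame(cell_id = segments$table$id,
                    call = character(n), votes_luminal = integer(n),
                    votes_basal = integer(n), excluded = logical(n),
                    reason = rep(NA_character_, n))
  for (i in seq_len(n)) {
    lc <- classify_cell(segments$voxels[[i]], k8$data, sma$data, params,
                        duct = duct, cell_radius = cell_radius,
                        spacing = segments$spacing)
    out$call[i] <- lc$call
    out$votes_luminal[i] <- sum(lc$votes$vote == "luminal")
    out$votes_basal[i] <- sum(lc$votes$vote == "basal")
    out$excluded[i] <- !is.null(lc$exclusion_reason)
    out$reason[i] <- if (is.null(lc$exclusion_reason)) NA_character_ else
      lc$exclusion_reason
  }
  out
}
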