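#' Volumetric ratio of labelled cells to ductal cellular volume
#'
#' @param cell_labels integer 3D array of detected cell labels (0 =
#'   background), already restricted to the duct.
#' @param duct a `duct_model` with nonzero volume.
#' @param region_mask optional logical array restricting the computation
#'   to one duct region (a connected component of the duct mask).
#' @param denominator "duct" (duct-mask voxels, the duct volume measure)
#'   or "significant" (significant cellular voxels within the duct, e.g.
#'   the SMA-significant basal compartment for the basal variant).
#' @param region_id identifier recorded in the result.
#' @return a `region_quantification`: list(region_id,
#'   eyfp_volume_voxels, duct_volume_voxels, ratio).
#' @export
volumetric_ratio <- function(cell_labels, duct, region_mask = NULL,
                             denominator = c("duct", "significant"),
                             region_id = 1L) {
  stopifnot(inherits(duct, "duct_model"))
  denominator <- match.arg(denominator)
  base <- if (denominator == "significant") {
    if (is.null(duct$significant_mask))
      stop("duct model has no significant_mask")
    duct$significant_mask
  } else duct$duct_mask
  if (!is.null(region_mask)) base <- base & region_mask
  denom <- sum(base)
  if (denom == 0) stop("duct volume is zero in this region")
  inreg <- cell_labels > 0L
  if (!is.null(region_mask)) inreg <- inreg & region_mask
  inreg <- inreg & duct$duct_mask
  num <- sum(inreg)
  structure(list(region_id = region_id,
                 eyfp_volume_voxels = num,
                 duct_volume_voxels = denom,
                 ratio = min(num / denom, 1)),
            class = "region_quantification")
}

#' Mean and sample standard deviation of region ratios
#'
#' @param regions list of `region_quantification` objects (or a numeric
#'   vector of ratios).
#' @return list(mean, sd, n); sd is 0 (flagged via `single_region`) for a
#'   single region.
#' @export
summarize_regions <- function(regions) {
  ratios <- if (is.numeric(regions)) regions else
    vapply(regions, function(r) r$ratio, numeric(1))
  if (length(ratios) == 0L) stop("at least one region is required")
  list(mean = mean(ratios),
       sd = if (length(ratios) > 1) stats::sd(ratios) else 0,
       n = length(ratios),
       single_region = length(ratios) == 1L)
}

#' Kolmogorov-Smirnov comparison of K8 intensity distributions
#'
#' Two-sample KS test of the K8 intensities at the duct's significant
#' voxels against those inside the segmented EYFP+ cells (restricted to
#' significant voxels), asking whether the EYFP label is over-represented
#' in the K8-high subpopulation.
#'
#' @param duct_k8 K8 intensities of the duct's significant voxels.
#' @param cell_k8 K8 intensities of the significant voxels inside EYFP+
#'   cells.
#' @param exact passed to [stats::ks.test()]; default lets ks.test decide.
#' @return list(statistic, p, direction) with direction "hi-enriched"
#'   when the cell sample stochastically dominates the duct sample at the
#'   KS location, "lo-enriched" for the reverse, "none" for identical
#'   distributions.
#' @export
ks_k8_distribution <- function(duct_k8, cell_k8, exact = NULL) {
  if (length(duct_k8) == 0L || length(cell_k8) == 0L)
    stop("both samples must be nonempty")
  if (length(duct_k8) < 5L || length(cell_k8) < 5L)
    warning("a sample has fewer than 5 voxels; the KS p-value is unreliable")
  kt <- suppressWarnings(stats::ks.test(cell_k8, duct_k8, exact = exact))
  stat <- unname(kt$statistic)
  direction <- "none"
  if (stat > 0) {
    # sign of (F_duct - F_cell) at the supremum location
    xs <- sort(unique(c(duct_k8, cell_k8)))
    fd <- stats::ecdf(duct_k8)(xs)
    fc <- stats::ecdf(cell_k8)(xs)
    at <- which.max(abs(fd - fc))
    direction <- if (fd[at] > fc[at]) "hi-enriched" else "lo-enriched"
  }
  list(statistic = stat, p = unname(kt$p.value), direction = direction)
}

#' Minimum progenitor estimate from the mean volumetric ratio
#'
#' Under the assumption that all stem/progenitors contribute equally to
#' ductal outgrowth, the reciprocal of the mean labelled-volume ratio is
#' the implied minimum number of contributing progenitors (a mean ratio
#' of 4.7% implies at least ~21 cells).
#'
#' @param mean_ratio mean volumetric ratio in (0, 1].
#' @return the raw reciprocal 1 / mean_ratio.
#' @export
min_progenitor_estimate <- function(mean_ratio) {
  if (!is.numeric(mean_ratio) || mean_ratio <= 0 || mean_ratio > 1)
    stop("mean_ratio must lie in (0, 1]")
  1 / mean_ratio
}

# conservative printed bound: reciprocal floored to the nearest lower
# multiple of 5 (21.3 -> "at least 20")
floor_to_5 <- function(x) 5 * floor(x / 5)

#' Group labelled regions into clones by physical separation
#'
#' Labelled regions whose nearest surface-to-surface distance is at most
#' `min_separation` are merged (transitively, i.e. single linkage) into
#' one clone; distinct labelled regions separated by more than the
#' threshold (default 1 mm) count as separate clones.
#'
#' @param region_points list of matrices of voxel indices (rows = voxels,
#'   columns = i, j, k) or physical coordinate matrices (um) when
#'   `physical = TRUE`, one per labelled region.
#' @param spacing voxel spacing, um (ignored when `physical = TRUE`).
#' @param min_separation merge threshold, um (default 1000 = 1 mm).
#' @param physical set TRUE when `region_points` already holds um
#'   coordinates.
#' @return list(assignments = integer clone id per region, clone_count).
#' @export
group_clones <- function(region_points, spacing = c(1, 1, 1),
                         min_separation = 1000, physical = FALSE) {
  n <- length(region_points)
  if (n == 0L) return(list(assignments = integer(), clone_count = 0L))
  coords <- lapply(region_points, function(m) {
    m <- as.matrix(m)
    if (physical) m else voxel_centres_um(m, spacing)
  })
  # union-find over pairwise nearest distances
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dmin <- min_pointset_distance(coords[[i]], coords[[j]])
      if (dmin <= min_separation) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  assignments <- match(roots, unique(roots))
  list(assignments = assignments, clone_count = length(unique(assignments)))
}

min_pointset_distance <- function(a, b) {
  # chunked to bound memory on large regions
  best <- Inf
  step <- 2000L
  for (s in seq(1, nrow(a), by = step)) {
    ai <- a[s:min(s + step - 1L, nrow(a)), , drop = FALSE]
    for (t in seq(1, nrow(b), by = step)) {
      bi <- b[t:min(t + step - 1L, nrow(b)), , drop = FALSE]
      d2 <- outer(rowSums(ai^2), rowSums(bi^2), `+`) - 2 * ai %*% t(bi)
      best <- min(best, sqrt(max(min(d2), 0)))
    }
  }
  best
}

#' Alveolar occupancy counts
#'
#' For each alveolus, computes the fraction of that lineage's cells that
#' are EYFP+: at least `full_fraction` counts as fully populated, a
#' nonzero fraction below it as partially populated, zero is not counted.
#'
#' @param cells data.frame with columns `alveolus_id`, `lineage`,
#'   `labelled` (logical), e.g. a ground-truth registry or detected calls
#'   joined to alveolus instances.
#' @param lineage "luminal" or "basal".
#' @param full_fraction threshold for "fully populated" (default 0.95,
#'   tolerating segmentation error).
#' @return list(n_full, n_partial, per_alveolus data.frame).
#' @export
alveolar_occupancy <- function(cells, lineage, full_fraction = 0.95) {
  cells <- cells[cells$lineage == lineage, , drop = FALSE]
  if (nrow(cells) == 0L)
    return(list(n_full = 0L, n_partial = 0L,
                per_alveolus = data.frame(alveolus_id = integer(),
                                          fraction = numeric(),
                                          status = character())))
  frac <- tapply(cells$labelled, cells$alveolus_id, mean)
  status <- ifelse(frac >= full_fraction, "full",
                   ifelse(frac > 0, "partial", "unlabelled"))
  list(n_full = sum(status == "full"),
       n_partial = sum(status == "partial"),
       per_alveolus = data.frame(alveolus_id = names(frac),
                                 fraction = as.numeric(frac),
                                 status = as.character(status),
                                 row.names = NULL))
}

#' Assemble a clone report
#'
#' @param regions list of `region_quantification` objects.
#' @param ks optional result of [ks_k8_distribution()].
#' @param clone_count optional clone count from [group_clones()].
#' @param alveoli optional result of [alveolar_occupancy()].
#' @return a `clone_report`: regions, mean/sd ratio, min-progenitor
#'   estimate (raw and floored to the nearest 5), KS results, clone and
#'   alveolar counts.
#' @export
clone_report <- function(regions, ks = NULL, clone_count = NULL,
                         alveoli = NULL) {
  s <- summarize_regions(regions)
  rep <- list(regions = regions, mean_ratio = s$mean, sd_ratio = s$sd,
              n_regions = s$n)
  rep$min_progenitors <- if (s$mean > 0) min_progenitor_estimate(s$mean) else NA
  rep$min_progenitors_bound <- if (s$mean > 0) floor_to_5(rep$min_progenitors) else NA
  if (!is.null(ks)) {
    rep$ks_statistic <- ks$statistic
    rep$ks_p <- ks$p
    rep$ks_direction <- ks$direction
  }
  if (!is.null(clone_count)) rep$clone_count <- clone_count
  if (!is.null(alveoli)) {
    rep$alveoli_full <- alveoli$n_full
    rep$alveoli_partial <- alveoli$n_partial
  }
  structure(rep, class = "clone_report")
}

#' @export
print.clone_report <- function(x, ...) {
  cat(sprintf("<clone_report> %d region(s): ratio %.3f +/- %.3f",
              x$n_regions, x$mean_ratio, x$sd_ratio))
  if (!is.null(x$min_progenitors) && !is.na(x$min_progenitors))
    cat(sprintf(" -> >= %d progenitors (raw %.1f)",
                x$min_progenitors_bound, x$min_progenitors))
  cat("\n")
  invisible(x)
}
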