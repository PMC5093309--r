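#' Pipeline configuration
#'
#' Bundles all module parameter blocks and validates them before any
#' computation.
#'
#' @param cell_radius expected cell radius in um; drives the detection
#'   defaults and the SMA-exclusion dilation radius.
#' @param spacing voxel spacing (um); needed to express default sizes in
#'   voxels.
#' @param wavelet a `wavelet_params` block.
#' @param detection a `detection_params` block (default derived from
#'   `cell_radius` and `spacing`).
#' @param classification a `classification_params` block.
#' @param restoration a `restoration_params` block (basal variant only).
#' @param ratio_denominator "all_cellular" (duct-mask volume, the default
#'   for the ductal/luminal analysis) or "lineage_compartment"
#'   (lineage-marker significant voxels within the duct, the default for
#'   the basal variant where the ratio is taken against the basal
#'   cellular volume).
#' @param min_separation clone-grouping separation threshold, um.
#' @param min_region_volume minimum duct-region volume (um^3) entering
#'   the per-region ratio statistics; smaller connected components of the
#'   duct mask are treated as segmentation debris.
#' @param ks_mode "pooled" (one KS test over all EYFP+ cells, default) or
#'   "per_cell".
#' @param keep_intermediates retain masks and filtered grids in the
#'   result.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(cell_radius = 3.5,
                            spacing = c(0.5, 0.5, 2),
                            wavelet = wavelet_params(),
                            detection = NULL,
                            classification = classification_params(),
                            restoration = restoration_params(),
                            ratio_denominator = NULL,
                            min_separation = 1000,
                            min_region_volume = 500,
                            ks_mode = c("pooled", "per_cell"),
                            keep_intermediates = FALSE) {
  if (is.null(detection))
    detection <- default_detection_params(cell_radius, spacing)
  stopifnot(inherits(wavelet, "wavelet_params"),
            inherits(detection, "detection_params"),
            inherits(classification, "classification_params"),
            inherits(restoration, "restoration_params"))
  ks_mode <- match.arg(ks_mode)
  structure(list(cell_radius = cell_radius, spacing = spacing,
                 wavelet = wavelet, detection = detection,
                 classification = classification, restoration = restoration,
                 ratio_denominator = ratio_denominator,
                 min_separation = min_separation,
                 min_region_volume = min_region_volume, ks_mode = ks_mode,
                 keep_intermediates = isTRUE(keep_intermediates)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

# regions = connected components of the duct mask, excluding fragments
# below min_region_volume (um^3; segmentation debris cannot hold even a
# handful of cells and would distort the per-region ratio statistics);
# returns region quantifications plus per-region labelled voxel indices.
# Index-based equivalent of volumetric_ratio() over each component.
quantify_regions <- function(cells, duct, denominator, spacing,
                             min_region_volume = 500) {
  comp <- label_components(duct$duct_mask, 26L)
  induct <- which(comp > 0L)
  if (length(induct) == 0L)
    return(list(regions = list(), labelled_sets = list()))
  byreg <- split(induct, comp[induct])
  vox_vol <- prod(spacing)
  sizes <- vapply(byreg, length, integer(1))
  keep <- sizes * vox_vol >= min_region_volume
  if (!any(keep)) keep <- sizes == max(sizes)
  regions <- list()
  labelled_sets <- list()
  rid <- 0L
  for (k in which(keep)) {
    idx <- byreg[[k]]
    denom <- if (denominator == "lineage_compartment")
      sum(duct$significant_mask[idx]) else length(idx)
    if (denom == 0L) next  # no quantifiable compartment in this region
    lin <- idx[cells$labels[idx] > 0L]
    rid <- rid + 1L
    regions[[rid]] <- structure(
      list(region_id = rid,
           eyfp_volume_voxels = length(lin),
           duct_volume_voxels = denom,
           ratio = min(length(lin) / denom, 1)),
      class = "region_quantification")
    labelled_sets[[rid]] <- lin
  }
  list(regions = regions, labelled_sets = labelled_sets)
}

pooled_ks <- function(cells, duct, k8) {
  sig <- duct$significant_mask
  duct_vals <- k8$data[sig]
  cell_sig <- cells$labels > 0L & sig
  cell_vals <- k8$data[cell_sig]
  if (length(duct_vals) < 5L || length(cell_vals) < 5L) return(NULL)
  ks_k8_distribution(duct_vals, cell_vals)
}

finalize_result <- function(stack, config, duct, cells, calls, variant,
                            intermediates = NULL) {
  k8 <- stack_channel(stack, "K8")
  denom <- config$ratio_denominator
  if (is.null(denom))
    denom <- if (variant == "basal") "lineage_compartment" else "all_cellular"
  q <- run_stage("quantification",
                 quantify_regions(cells, duct, denom, stack$spacing,
                                  config$min_region_volume))
  ks <- run_stage("ks", pooled_ks(cells, duct, k8))
  # clone grouping over the per-region labelled voxel sets (downsampled:
  # the 1 mm separation scale does not need voxel-level resolution)
  nonempty <- which(vapply(q$labelled_sets, length, 1L) > 0)
  grouping <- if (length(nonempty) > 0) {
    pts <- lapply(q$labelled_sets[nonempty], function(lin) {
      idx <- arrayInd(lin, dim(k8$data))
      if (nrow(idx) > 1500) idx <- idx[seq(1, nrow(idx), length.out = 1500), ,
                                       drop = FALSE]
      idx
    })
    group_clones(pts, spacing = stack$spacing,
                 min_separation = config$min_separation)
  } else list(assignments = integer(), clone_count = 0L)
  report <- if (length(q$regions) > 0) {
    clone_report(q$regions, ks = ks, clone_count = grouping$clone_count)
  } else {
    structure(list(regions = list(), mean_ratio = NA_real_,
                   sd_ratio = NA_real_, n_regions = 0L,
                   min_progenitors = NA, min_progenitors_bound = NA,
                   clone_count = 0L),
              class = "clone_report")
  }
  res <- list(duct = duct, cells = cells, calls = calls, report = report,
              variant = variant,
              thresholds_used = intermediates$thresholds_used,
              config = config)
  if (config$keep_intermediates) res$intermediates <- intermediates
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> (%s variant)\n", x$variant))
  print(x$duct)
  print(x$cells)
  if (nrow(x$calls) > 0) {
    tb <- table(x$calls$call)
    cat("  calls:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  print(x$report)
  invisible(x)
}

#' Run the ductal (luminal-clone) analysis
#'
#' The full analysis in the fixed order: duct segmentation from the K8
#' channel, significant-voxel detection within the duct, independent
#' EYFP+ cell detection restricted to the duct, per-cell luminal/basal
#' classification, and volumetric quantification with KS comparison and
#' clone grouping.
#'
#' @param stack a `multichannel_stack` with channels EYFP, K8, SMA.
#' @param config a `pipeline_config`.
#' @return a `pipeline_result`.
#' @export
run_ductal <- function(stack, config = pipeline_config(spacing = stack$spacing)) {
  stopifnot(inherits(stack, "multichannel_stack"))
  k8 <- stack_channel(stack, "K8")
  sma <- stack_channel(stack, "SMA")
  eyfp <- stack_channel(stack, "EYFP")
  duct <- run_stage("duct segmentation", segment_duct(k8, config$wavelet))
  sig <- run_stage("significant voxels",
                   detect_significant_voxels(k8, duct, config$wavelet$fdr_q))
  duct <- set_significant_mask(duct, sig)
  cells <- run_stage("cell detection",
                     detect_eyfp_cells(eyfp, duct, config$detection))
  calls <- run_stage("classification",
                     classify_segments(cells, k8, sma, config$classification,
                                       duct = duct,
                                       cell_radius = config$cell_radius))
  finalize_result(stack, config, duct, cells, calls, "ductal",
                  intermediates = list(
                    thresholds_used = c(
                      dog = attr(cells, "dog_threshold"))))
}

#' Run the basal-clone analysis variant
#'
#' As [run_ductal()], with the modifications needed for the deeper,
#' noisier basal-clone stacks: restoration (denoising then deblurring)
#' of all channels precedes detection, every channel is segmented in 3D
#' so the duct mask is the union of the K8 (luminal) and SMA (basal)
#' coarse segmentations, the EYFP segmentation is split by a seeded
#' watershed to separate elongated overlapping cells, the
#' SMA-undetectable exclusion is applied, and the volumetric ratio is
#' taken against the basal (SMA-significant) compartment by default.
#'
#' @param stack a `multichannel_stack` with channels EYFP, K8, SMA.
#' @param config a `pipeline_config`; the default uses
#'   [elongated_detection_params()] (spindle-shaped cells) and 30
#'   deblurring iterations (thin deep cells need the stronger
#'   restoration to rise above the detection threshold).
#' @return a `pipeline_result`.
#' @export
run_basal_variant <- function(stack,
                              config = pipeline_config(
                                spacing = stack$spacing,
                                detection = elongated_detection_params(
                                  3.5, stack$spacing),
                                restoration = restoration_params(
                                  deblur_iterations = 30L))) {
  stopifnot(inherits(stack, "multichannel_stack"))
  restore <- function(name) {
    g <- stack_channel(stack, name)
    g <- run_stage(paste("denoise", name),
                   denoise_stack(g, config$restoration))
    run_stage(paste("deblur", name), deblur_stack(g, config$restoration))
  }
  eyfp <- restore("EYFP")
  k8 <- restore("K8")
  sma <- restore("SMA")
  # In the basal analysis every channel is segmented in 3D: the duct is
  # the bilayer, so its mask is the union of the K8 (inner luminal) and
  # SMA (outer basal) coarse segmentations.  A K8-only mask would clip
  # away the very compartment under study.
  duct_k8 <- run_stage("duct segmentation", segment_duct(k8, config$wavelet))
  duct_sma <- run_stage("duct segmentation (SMA)",
                        segment_duct(sma, config$wavelet))
  duct <- new_duct_model(duct_k8$duct_mask | duct_sma$duct_mask)
  # basal compartment: SMA-significant voxels within the duct
  sig <- run_stage("significant voxels",
                   detect_significant_voxels(sma, duct, config$wavelet$fdr_q))
  duct <- set_significant_mask(duct, sig)
  # EYFP segmentation: threshold, drop undersized connected components
  # (the size rule applies to components, as in the ductal path), then
  # split what remains by the seeded watershed and clip to the duct.  A
  # watershed basin may be smaller than min_cell_size when it is the
  # marginal part of a large merged component; it is kept, since its
  # component passed the size rule.
  dog <- dog_filter(eyfp, config$detection)
  thr <- robust_threshold(as.numeric(dog$data))
  mask <- dog$data > thr
  comp <- label_components(mask, 26L)
  if (any(comp > 0L)) {
    csz <- tabulate(comp)
    small <- comp > 0L & array(csz[pmax(comp, 1L)] <
                               config$detection$min_cell_size, dim(comp))
    mask[small] <- FALSE
  }
  labels <- run_stage("watershed",
                      watershed_split(mask, config$detection, stack$spacing))
  labels[!duct$duct_mask] <- 0L
  cells <- segments_from_labels(labels, stack$spacing)
  calls <- run_stage("classification",
                     classify_segments(cells, k8, sma, config$classification,
                                       duct = duct,
                                       cell_radius = config$cell_radius))
  finalize_result(stack, config, duct, cells, calls, "basal",
                  intermediates = list(thresholds_used = c(dog = thr)))
}
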