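# Stack and report IO: multi-page TIFF with a JSON sidecar carrying
# channel names and voxel spacing (the portable equivalent of the
# proprietary microscope format), ground truth as CSV + JSON, reports as
# JSON + CSV. All physical quantities are serialized in um; voxel
# coordinates are 0-based in the files.

#' Write a multi-channel stack as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered z-within-channel. Intensities are stored on the
#' 12-bit (0-4095) scale in 16-bit samples; integer stacks round-trip
#' losslessly.
#'
#' @param stack a `multichannel_stack`.
#' @param path output TIFF path; the sidecar is written next to it with
#'   extension ".json".
#' @return invisibly, the sidecar metadata list.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "multichannel_stack"))
  d <- dim(stack$channels[[1]])
  pages <- list()
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    for (z in seq_len(d[3]))
      # TIFF rows are the first index; store the transpose so x is width
      pages[[length(pages) + 1]] <- t(arr[, , z]) / 4095
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = names(stack$channels),
               shape_voxels = d,
               spacing_um = stack$spacing,
               bit_depth = 12L,
               page_order = "z-within-channel")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(meta)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Read a multi-channel stack
#'
#' Reads a multi-page TIFF written by [write_stack()] (channel names and
#' spacing from the JSON sidecar), or a plain multi-page TIFF with
#' channel order and spacing supplied explicitly.
#'
#' @param path TIFF path.
#' @param expected_channels channel names that must be present.
#' @param channels channel order for plain TIFFs without a sidecar.
#' @param spacing voxel spacing for plain TIFFs without a sidecar.
#' @return a `multichannel_stack`.
#' @export
read_stack <- function(path, expected_channels = c("EYFP", "K8", "SMA"),
                       channels = NULL, spacing = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    channels <- meta$channels
    spacing <- meta$spacing_um
  } else {
    if (is.null(channels))
      stop("plain TIFF without sidecar: supply `channels` (ordered names)")
    if (is.null(spacing))
      stop("plain TIFF without sidecar: supply `spacing` (um)")
  }
  missing <- setdiff(expected_channels, channels)
  if (length(missing) > 0)
    stop(sprintf("missing channel(s) %s; found: %s",
                 paste(missing, collapse = ", "),
                 paste(channels, collapse = ", ")))
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages) / length(channels)
  if (nz != round(nz))
    stop(sprintf("page count %d is not a multiple of %d channels",
                 length(pages), length(channels)))
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), as.integer(nz))
  chans <- list()
  p <- 1L
  for (ch in channels) {
    arr <- array(0, d)
    for (z in seq_len(d[3])) {
      arr[, , z] <- t(pages[[p]]) * 4095
      p <- p + 1L
    }
    chans[[ch]] <- round(arr)
  }
  multichannel_stack(chans, spacing)
}

#' Write ground truth (cell table as CSV, tree/config as JSON)
#'
#' @param truth a `ground_truth` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells_path <- file.path(dir, "cells.csv")
  utils::write.csv(as.data.frame(truth$registry), cells_path,
                   row.names = FALSE)
  meta <- list(
    tree = list(nodes = truth$tree$nodes, edges = truth$tree$edges,
                root = truth$tree$root),
    true_label_fraction = truth$true_label_fraction,
    seed = truth$seed,
    config = truth$config[setdiff(names(truth$config), "intensity_levels")],
    intensity_levels = as.list(truth$config$intensity_levels))
  meta_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(c(cells = cells_path, meta = meta_path))
}

#' Write a binary mask as 8-bit multi-page TIFF
#'
#' @param mask logical 3D array.
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  d <- dim(mask)
  pages <- lapply(seq_len(d[3]), function(z) t(mask[, , z]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a labeled mask as 16-bit multi-page TIFF
#'
#' @param labels integer 3D array (labels 0..65535).
#' @param path output path.
#' @export
write_labels_tiff <- function(labels, path) {
  d <- dim(labels)
  pages <- lapply(seq_len(d[3]), function(z) t(labels[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

report_to_list <- function(report) {
  out <- unclass(report)
  out$regions <- lapply(report$regions, function(r)
    list(region_id = r$region_id,
         eyfp_volume_voxels = r$eyfp_volume_voxels,
         duct_volume_voxels = r$duct_volume_voxels,
         ratio = r$ratio))
  out
}

#' Write a clone report as JSON + CSV
#'
#' Writes `report.json` (all summary fields, stable key order, 6
#' significant digits) and `regions.csv` (one row per region).
#'
#' @param report a `clone_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "clone_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), json_path, auto_unbox = TRUE,
                       digits = I(6), pretty = TRUE, na = "null")
  csv_path <- file.path(dir, "regions.csv")
  regions <- do.call(rbind, lapply(report$regions, function(r)
    data.frame(region_id = r$region_id,
               eyfp_volume_voxels = r$eyfp_volume_voxels,
               duct_volume_voxels = r$duct_volume_voxels,
               ratio = signif(r$ratio, 6))))
  utils::write.csv(regions, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Read back a clone report written by [write_report()]
#'
#' @param dir directory containing `report.json`.
#' @return a `clone_report`.
#' @export
read_report <- function(dir) {
  x <- jsonlite::read_json(file.path(dir, "report.json"),
                           simplifyVector = FALSE)
  x$regions <- lapply(x$regions, function(r) {
    structure(r, class = "region_quantification")
  })
  structure(x, class = "clone_report")
}
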