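# Shared simulation cache: several test files exercise the same synthetic
# stacks; generating each once keeps the suite fast.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (!exists(key, envir = .sim_cache))
    assign(key, simulate_stack(config), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# small, quick ductal scene used by several unit tests
small_ductal_sim <- function() {
  cached_sim("small_ductal", sim_config(
    grid_shape = c(128L, 128L, 32L), duct_radius = 12, tree_depth = 0L,
    seed = 7, target_label_fraction = 0.1))
}

# scattered labelled cells: well-separated, for detection oracles
scattered_sim <- function(seed, f) {
  cached_sim(sprintf("scat_%d_%g", seed, f), sim_config(
    seed = seed, target_label_fraction = f, label_pattern = "scattered"))
}

# map every ground-truth labelled cell to the call of the segment that
# covers most of it ("undetected" when no segment voxel overlaps it)
truth_cell_calls <- function(sim, res) {
  lm <- sim$truth$label_map
  lab_ids <- sim$truth$registry$id[sim$truth$registry$eyfp]
  vapply(lab_ids, function(cid) {
    vox <- which(lm == cid)
    segs <- res$cells$labels[vox]
    segs <- segs[segs > 0]
    if (length(segs) == 0) return("undetected")
    sid <- as.integer(names(which.max(table(segs))))
    res$calls$call[res$calls$cell_id == sid]
  }, character(1))
}

# detection precision/recall against ground-truth centres (match radius
# = cell_radius, as in the spec's detection property)
detection_pr <- function(sim, res) {
  reg <- sim$truth$registry
  truth <- reg[reg$eyfp, c("x", "y", "z")]
  cent <- res$cells$table[, c("cx", "cy", "cz")]
  r <- sim$truth$config$cell_radius
  if (nrow(cent) == 0) return(c(precision = NA, recall = 0))
  dmat <- sqrt(outer(truth$x, cent$cx, `-`)^2 +
               outer(truth$y, cent$cy, `-`)^2 +
               outer(truth$z, cent$cz, `-`)^2)
  c(precision = mean(apply(dmat, 2, min) <= r),
    recall = mean(apply(dmat, 1, min) <= r))
}
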