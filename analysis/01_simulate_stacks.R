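#!/usr/bin/env Rscript
# Generate the synthetic stacks used by the downstream analysis drivers:
# a ductal luminal-clone stack, a deeper basal-clone stack, and a
# scattered-label stack for detection sanity checks. Writes multi-page
# TIFFs with JSON sidecars plus ground truth under results/data/.

suppressPackageStartupMessages(library(clonemap3d))

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

make <- function(name, cfg) {
  message("simulating ", name, " ...")
  sim <- simulate_stack(cfg)
  write_stack(sim$stack, file.path(out, paste0(name, ".tif")))
  write_ground_truth(sim$truth, file.path(out, paste0(name, "_truth")))
  message(sprintf("  %d cells (%d labelled), true labelled fraction %.4f",
                  nrow(sim$truth$registry), sum(sim$truth$registry$eyfp),
                  sim$truth$true_label_fraction))
  invisible(sim)
}

make("ductal", sim_config(seed = 1001, target_label_fraction = 0.05))
make("basal", sim_config(seed = 1002, founder_lineage = "basal",
                         target_label_fraction = 0.16,
                         grid_shape = c(256L, 256L, 96L),
                         voxel_spacing = c(0.5, 0.5, 1)))
make("scattered", sim_config(seed = 1003, target_label_fraction = 0.06,
                             label_pattern = "scattered"))

message("done; stacks in ", out)
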