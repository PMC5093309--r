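test_that("sim_config validates its fields", {
  expect_error(sim_config(target_label_fraction = 1.5), "\\[0, ?1\\]|in \\[0")
  expect_error(sim_config(duct_radius = -1))
  expect_error(sim_config(attenuation_length = 0), "positive")
  cfg <- sim_config(seed = 3)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$founder_lineage, "luminal")
})

test_that("cell placement honours the lineage geometry invariants", {
  sim <- small_ductal_sim()
  reg <- sim$truth$registry
  tree <- sim$truth$tree
  # distance of each cell centre from the duct axis (single-segment tree)
  e <- tree$edges[1, ]
  p0 <- as.numeric(tree$nodes[tree$nodes$id == e$from, c("x", "y", "z")])
  p1 <- as.numeric(tree$nodes[tree$nodes$id == e$to, c("x", "y", "z")])
  u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  rad <- vapply(seq_len(nrow(reg)), function(i) {
    v <- c(reg$x[i], reg$y[i], reg$z[i]) - p0
    t <- sum(v * u)
    sqrt(sum((v - t * u)^2))
  }, numeric(1))
  R <- e$radius
  lum <- reg$lineage == "luminal"
  r <- sim$truth$config$cell_radius
  expect_true(all(rad[lum] < R))                    # luminal strictly inside
  expect_true(all(abs(rad[!lum] - R) <= r))         # basal on the surface
  # basal cells are elongated with axis ratio >= 2
  expect_true(all(reg$ax[!lum] / reg$bx[!lum] >= 2))
})

test_that("EYFP labels only the founder lineage and hits the volume target", {
  sim <- small_ductal_sim()
  reg <- sim$truth$registry
  expect_true(all(reg$lineage[reg$eyfp] == "luminal"))
  f <- sim$truth$config$target_label_fraction
  expect_lt(abs(sim$truth$true_label_fraction - f) / f, 0.2)
})

test_that("unreachable label fractions error", {
  expect_error(
    simulate_stack(sim_config(grid_shape = c(128L, 128L, 32L),
                              duct_radius = 12, tree_depth = 0L, seed = 7,
                              founder_lineage = "basal",
                              target_label_fraction = 0.9)),
    "unreachable")
})

test_that("marker channels are lineage-exclusive before autofluorescence", {
  cfg <- sim_config(grid_shape = c(128L, 128L, 32L), duct_radius = 12,
                    tree_depth = 0L, seed = 9, target_label_fraction = 0.1,
                    af_level = 0, psf_sigma = c(1e-6, 1e-6),
                    noise_gain = 0, noise_read_sd = 0)
  sim <- simulate_stack(cfg)
  lm <- sim$truth$label_map
  reg <- sim$truth$registry
  lum_vox <- lm %in% reg$id[reg$lineage == "luminal"]
  bas_vox <- lm %in% reg$id[reg$lineage == "basal"]
  sma <- sim$truth$clean_channels$SMA
  k8 <- sim$truth$clean_channels$K8
  expect_true(all(sma[lum_vox] < 1e-6))   # SMA zero at luminal-only voxels
  expect_true(all(k8[bas_vox] < 1e-6))    # K8 zero at basal-only voxels
  expect_true(all(k8[lum_vox] > 0))
})

test_that("geometry and noise seeds are independent streams", {
  base <- sim_config(grid_shape = c(128L, 128L, 32L), duct_radius = 12,
                     tree_depth = 0L, seed = 7, target_label_fraction = 0.1)
  s1 <- small_ductal_sim()
  s2 <- simulate_stack(base)                       # identical everything
  expect_identical(s1$stack$channels$EYFP, s2$stack$channels$EYFP)
  cfg3 <- sim_config(grid_shape = c(128L, 128L, 32L), duct_radius = 12,
                     tree_depth = 0L, seed = 7, target_label_fraction = 0.1,
                     noise_seed = 4242)
  s3 <- simulate_stack(cfg3)
  # same geometry / ground truth, different noise draw
  expect_identical(s1$truth$label_map, s3$truth$label_map)
  expect_identical(s1$truth$clean_channels$K8, s3$truth$clean_channels$K8)
  expect_false(identical(s1$stack$channels$K8, s3$stack$channels$K8))
})

test_that("intensities are quantized 12-bit and the af field is bounded", {
  sim <- small_ductal_sim()
  for (ch in sim$stack$channels) {
    expect_true(all(ch >= 0 & ch <= 4095))
    expect_true(all(ch == round(ch)))
  }
  cfg <- sim$truth$config
  af <- clonemap3d:::autofluorescence_field(cfg)
  expect_true(all(af >= 0 & af <= cfg$af_level))
})

test_that("alveolar mode renders sparse K8-hi and alveolus-attached cells", {
  sim <- cached_sim("alv", sim_config(
    grid_shape = c(192L, 192L, 48L), mode = "alveolar", seed = 21,
    target_label_fraction = 0.2))
  reg <- sim$truth$registry
  expect_true(any(reg$structure == "alveolus"))
  lum <- reg[reg$lineage == "luminal", ]
  expect_lt(mean(lum$k8_class == "hi"), 0.1)  # "extremely sparse" K8-hi
})
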