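make_duct_stack <- function(seed = 30) {
  # bright tube along x in a dim textured background
  set.seed(seed)
  d <- c(64, 64, 16)
  a <- array(rnorm(prod(d), 100, 15), d)
  ctr <- c(32, 8)
  for (j in 1:64) for (k in 1:16) {
    if ((j - ctr[1])^2 / 14^2 + (k - ctr[2])^2 / 4^2 <= 1)
      a[, j, k] <- a[, j, k] + 1800
  }
  voxel_grid(pmax(a, 0), c(0.5, 0.5, 2))
}

test_that("segment_duct recovers a bright tube and reports its volume", {
  g <- make_duct_stack()
  duct <- segment_duct(g, wavelet_params(coarse_level = 2L))
  expect_s3_class(duct, "duct_model")
  expect_equal(duct$duct_volume_voxels, sum(duct$duct_mask))
  # tube interior covered, far corner background excluded
  expect_true(all(duct$duct_mask[, 28:36, 7:9]))
  expect_false(any(duct$duct_mask[, 55:64, 14:16]))
})

test_that("segment_duct warns and returns an empty mask when nothing is bright", {
  g <- voxel_grid(array(50, c(32, 32, 8)), c(1, 1, 1))
  expect_warning(duct <- segment_duct(g, wavelet_params(coarse_level = 2L)),
                 "empty mask")
  expect_equal(duct$duct_volume_voxels, 0L)
})

test_that("significant voxels are a subset of the duct and prefer lining over holes", {
  set.seed(31)
  d <- c(64, 64, 8)
  a <- array(rnorm(prod(d), 100, 10), d)
  # textured lining everywhere in the tube, smooth dark nuclei holes
  tube <- array(FALSE, d)
  tube[, 20:44, ] <- TRUE
  a[tube] <- a[tube] + 1500 + rnorm(sum(tube), 0, 300)
  holes <- array(FALSE, d)
  for (h in list(c(12, 30, 4), c(30, 26, 3), c(50, 38, 5)))
    holes[(h[1] - 2):(h[1] + 2), (h[2] - 2):(h[2] + 2), h[3]] <- TRUE
  a[holes] <- 100  # flat dark interior
  g <- voxel_grid(a, c(1, 1, 1))
  duct <- segment_duct(g, wavelet_params(coarse_level = 2L))
  sig <- detect_significant_voxels(g, duct)
  expect_true(all(!sig | duct$duct_mask))  # sig subset of duct
  lining <- tube & !holes & duct$duct_mask
  frac_hole <- mean(sig[holes & duct$duct_mask])
  frac_lining <- mean(sig[lining])
  expect_lt(frac_hole, frac_lining)
})

test_that("set_significant_mask enforces the subset invariant", {
  duct <- clonemap3d:::new_duct_model(array(c(TRUE, FALSE), c(4, 4, 2)))
  sig <- array(TRUE, c(4, 4, 2))
  duct <- set_significant_mask(duct, sig)
  expect_equal(duct$significant_mask, duct$duct_mask)
})

test_that("duct segmentation is deterministic", {
  g <- make_duct_stack()
  d1 <- segment_duct(g, wavelet_params(coarse_level = 2L))
  d2 <- segment_duct(g, wavelet_params(coarse_level = 2L))
  expect_identical(d1$duct_mask, d2$duct_mask)
})
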