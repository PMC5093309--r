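test_that("vote_at_threshold follows the literal rule, ties to basal", {
  expect_equal(vote_at_threshold(0, 0), "basal")
  expect_equal(vote_at_threshold(5, 5), "basal")
  expect_equal(vote_at_threshold(6, 5), "luminal")
  expect_equal(vote_at_threshold(5, 6), "basal")
  expect_error(vote_at_threshold(-1, 0), ">= 0")
})

test_that("count_lineage_voxels counts strict exceedances", {
  d <- c(6, 6, 2)
  k8 <- array(seq_len(prod(d)), d)
  sma <- array(rev(seq_len(prod(d))), d)
  vox <- c(1L, 10L, 50L, 72L)
  n <- count_lineage_voxels(vox, k8, sma, 49.5)
  expect_equal(unname(n[1]), sum(k8[vox] > 49.5))
  expect_equal(unname(n[2]), sum(sma[vox] > 49.5))
  # boundary: equality does not count
  expect_equal(unname(count_lineage_voxels(vox, k8, sma, 50)[1]),
               sum(k8[vox] > 50))
})

test_that("classify_cell majority vote on constructed intensity profiles", {
  d <- c(10, 10, 2)
  k8 <- array(0, d); sma <- array(0, d)
  vox <- 1:20
  # luminal: strong K8, no SMA
  k8[vox] <- 2000
  lc <- classify_cell(vox, k8, sma)
  expect_equal(lc$call, "luminal")
  expect_equal(nrow(lc$votes), 8L)
  expect_true(all(lc$votes$vote == "luminal"))
  # basal: strong SMA, weak K8 bleed-through
  k8[vox] <- 150; sma[vox] <- 1200
  expect_equal(classify_cell(vox, k8, sma)$call, "basal")
  # a 4-4 vote split is unclassified
  k8[] <- 0; sma[] <- 0
  k8[1:12] <- 800    # 12 voxels win thresholds 100..700 (4 luminal votes)
  sma[1:11] <- 1600  # 11 voxels win thresholds 900..1500 (4 basal votes)
  lc <- classify_cell(vox, k8, sma)
  expect_equal(sum(lc$votes$vote == "luminal"), 4L)
  expect_equal(lc$call, "unclassified")
})

test_that("classify_cell matches a brute-force oracle on random cells", {
  set.seed(60)
  d <- c(12, 12, 4)
  for (rep in 1:100) {
    k8 <- array(sample(0:2000, prod(d), TRUE), d)
    sma <- array(sample(0:2000, prod(d), TRUE), d)
    vox <- sample(prod(d), 30)
    lc <- classify_cell(vox, k8, sma)
    thr <- seq(100, 1500, by = 200)
    votes <- vapply(thr, function(t) {
      if (sum(k8[vox] > t) > sum(sma[vox] > t)) "luminal" else "basal"
    }, character(1))
    nl <- sum(votes == "luminal"); nb <- sum(votes == "basal")
    want <- if (nl > nb) "luminal" else if (nb > nl) "basal" else "unclassified"
    expect_equal(lc$call, want)
    expect_equal(lc$votes$vote, votes)
  }
})

test_that("cells in SMA-undetectable regions are excluded with a reason", {
  d <- c(24, 24, 8)
  sp <- c(1, 1, 1)
  duct <- clonemap3d:::new_duct_model(array(TRUE, d))
  k8 <- array(0, d)
  sma_dark <- array(0, d)             # SMA undetectable everywhere
  vox <- which(array(seq_len(prod(d)), d) <= 40)
  k8[vox] <- 50
  lc <- classify_cell(vox, k8, sma_dark, duct = duct, cell_radius = 3,
                      spacing = sp)
  expect_equal(lc$call, "unclassified")
  expect_match(lc$exclusion_reason, "undetectable")
  # with a detectable basal shell nearby the same cell is classified
  sma_ok <- array(500, d)
  lc2 <- classify_cell(vox, k8, sma_ok, duct = duct, cell_radius = 3,
                       spacing = sp)
  expect_equal(lc2$call, "basal")
  expect_null(lc2$exclusion_reason)
})

test_that("sma_detectable judges the dilated neighbourhood within the duct", {
  d <- c(20, 20, 6)
  duct_mask <- array(TRUE, d)
  duct <- clonemap3d:::new_duct_model(duct_mask)
  sma <- array(0, d)
  vox <- which(array(FALSE, d) | (slice.index(array(0, d), 1) %in% 9:11 &
                                  slice.index(array(0, d), 2) %in% 9:11 &
                                  slice.index(array(0, d), 3) == 3))
  # bright SMA patch just outside the cell: detectable via dilation
  sma[5:7, 8:12, 2:4] <- 400
  p <- classification_params()
  expect_true(sma_detectable(vox, sma, duct, p, cell_radius = 4,
                             spacing = c(1, 1, 1)))
  expect_false(sma_detectable(vox, sma, duct, p, cell_radius = 1,
                              spacing = c(1, 1, 1)))
})

test_that("classify_segments handles zero segments and thresholds rescale", {
  segs <- clonemap3d:::segments_from_labels(array(0L, c(8, 8, 2)), c(1, 1, 1))
  k8 <- voxel_grid(array(0, c(8, 8, 2)), c(1, 1, 1))
  out <- classify_segments(segs, k8, k8)
  expect_equal(nrow(out), 0L)
  p16 <- classification_params(intensity_scale = 16)
  expect_equal(p16$thresholds, 16 * seq(100, 1500, by = 200))
  expect_error(classification_params(thresholds = c(5, 4, 3)), "increasing")
})
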