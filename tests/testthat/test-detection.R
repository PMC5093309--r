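test_that("detection parameter constructors validate and derive sizes", {
  expect_error(detection_params(2, 1, 5L, 1), "sigma_small < sigma_large")
  expect_error(detection_params(1, 2, 0L, 1), "min_cell_size")
  p <- default_detection_params(3.5, c(0.5, 0.5, 2))
  expect_equal(p$sigma_small, 3.5 / 3)
  expect_equal(p$sigma_large, 10.5)
  expect_equal(p$min_cell_size,
               as.integer(round((4 / 3) * pi * 1.75^3 / 0.5)))
  pe <- elongated_detection_params(3.5, c(0.5, 0.5, 2))
  expect_lt(pe$min_cell_size, p$min_cell_size)
})

test_that("well-separated labelled cells are each detected once", {
  sim <- scattered_sim(12, 0.058)
  res <- run_ductal(sim$stack)
  n_true <- sum(sim$truth$registry$eyfp)
  expect_equal(nrow(res$cells$table), n_true)
  pr <- detection_pr(sim, res)
  expect_gte(pr["precision"], 0.9)
  expect_gte(pr["recall"], 0.9)
})

test_that("detection is equivariant to intensity scaling", {
  sim <- small_ductal_sim()
  eyfp <- stack_channel(sim$stack, "EYFP")
  k8 <- stack_channel(sim$stack, "K8")
  duct <- segment_duct(k8)
  p <- default_detection_params(3.5, sim$stack$spacing)
  s1 <- detect_eyfp_cells(eyfp, duct, p)
  eyfp2 <- voxel_grid(5 * eyfp$data, eyfp$spacing)
  s2 <- detect_eyfp_cells(eyfp2, duct, p)
  expect_identical(s1$labels, s2$labels)
  expect_equal(attr(s2, "dog_threshold"), 5 * attr(s1, "dog_threshold"))
})

test_that("cells outside the duct are not reported", {
  # bright blob far from the duct mask
  d <- c(48, 48, 12)
  set.seed(40)
  a <- array(rnorm(prod(d), 50, 8), d)
  blob <- function(ctr) {
    for (i in 1:48) for (j in 1:48) for (k in 1:12) {
      if ((i - ctr[1])^2 + (j - ctr[2])^2 + 4 * (k - ctr[3])^2 <= 16)
        a[i, j, k] <<- a[i, j, k] + 900
    }
  }
  blob(c(10, 10, 6))   # inside duct region
  blob(c(40, 40, 6))   # outside duct mask
  duct_mask <- array(FALSE, d)
  duct_mask[1:20, 1:20, ] <- TRUE
  duct <- clonemap3d:::new_duct_model(duct_mask)
  p <- detection_params(1, 6, 30L, 1)
  segs <- detect_eyfp_cells(voxel_grid(a, c(1, 1, 1)), duct, p)
  expect_equal(nrow(segs$table), 1L)
  expect_true(all(duct_mask[segs$voxels[[1]]]))
  expect_lt(max(abs(segs$table$cx[1] - 9.5), abs(segs$table$cy[1] - 9.5)), 4)
})

test_that("components below min_cell_size are removed", {
  d <- c(32, 32, 8)
  a <- array(0, d)
  a[16, 16, 4] <- 5000  # single hot voxel
  duct <- clonemap3d:::new_duct_model(array(TRUE, d))
  p <- detection_params(1, 6, 200L, 1)
  segs <- detect_eyfp_cells(voxel_grid(a, c(1, 1, 1)), duct, p)
  expect_equal(nrow(segs$table), 0L)
})

test_that("watershed_split obeys its contract on canonical cases", {
  # empty mask
  p <- detection_params(1, 4, 1L, 2)
  empty <- array(FALSE, c(8, 8, 4))
  expect_equal(watershed_split(empty, p, c(1, 1, 1)), array(0L, c(8, 8, 4)))
  # one convex blob -> one label
  d <- c(24, 24, 12)
  one <- array(FALSE, d)
  for (i in 1:24) for (j in 1:24) for (k in 1:12)
    if ((i - 12)^2 + (j - 12)^2 + (k - 6)^2 <= 25) one[i, j, k] <- TRUE
  lab <- watershed_split(one, p, c(1, 1, 1))
  expect_equal(max(lab), 1L)
  expect_equal(lab > 0L, one)
})

test_that("watershed splits two touching ellipsoids and partitions the mask", {
  d <- c(40, 24, 16)
  m <- array(FALSE, d)
  c1 <- c(14, 12, 8); c2 <- c(26, 12, 8)  # centres 1.5 long-axes apart
  for (i in 1:40) for (j in 1:24) for (k in 1:16) {
    if ((i - c1[1])^2 / 64 + (j - c1[2])^2 / 16 + (k - c1[3])^2 / 16 <= 1 ||
        (i - c2[1])^2 / 64 + (j - c2[2])^2 / 16 + (k - c2[3])^2 / 16 <= 1)
      m[i, j, k] <- TRUE
  }
  p <- detection_params(1, 4, 1L, 3)
  lab <- watershed_split(m, p, c(1, 1, 1))
  expect_equal(max(lab), 2L)
  expect_equal(lab > 0L, m)  # exact partition
  expect_true(lab[c1[1], c1[2], c1[3]] != lab[c2[1], c2[2], c2[3]])
})

test_that("watershed falls back to one seed per component with a warning", {
  d <- c(16, 16, 8)
  m <- array(FALSE, d)
  m[4:6, 4:6, 4] <- TRUE  # max distance ~1.5 < threshold
  p <- detection_params(1, 4, 1L, 5)
  expect_warning(lab <- watershed_split(m, p, c(1, 1, 1)),
                 "one seed per such component")
  expect_equal(max(lab), 1L)
  expect_equal(lab > 0L, m)
})

test_that("watershed partition invariant holds on random blobby masks", {
  set.seed(41)
  for (rep in 1:5) {
    d <- c(24, 24, 10)
    a <- array(rnorm(prod(d)), d)
    sm <- gaussian_blur(voxel_grid(a, c(1, 1, 1)), 2)$data
    m <- sm > quantile(sm, 0.85)
    p <- detection_params(1, 4, 1L, 1.2)
    lab <- suppressWarnings(watershed_split(m, p, c(1, 1, 1)))
    expect_equal(lab > 0L, m)
  }
})

test_that("seed_count_profile matches its definition at the extremes", {
  d <- c(32, 24, 12)
  m <- array(FALSE, d)
  for (i in 1:32) for (j in 1:24) for (k in 1:12) {
    if ((i - 9)^2 + (j - 12)^2 + (k - 6)^2 <= 16 ||
        (i - 23)^2 + (j - 12)^2 + (k - 6)^2 <= 16)
      m[i, j, k] <- TRUE
  }
  prof <- seed_count_profile(m, c(1, 1, 1), thresholds = c(0, 1, 2, 10))
  expect_equal(prof$n_seeds[1], max(label_components(m, 26L)))
  expect_equal(prof$n_seeds[prof$threshold == 10], 0L)
  expect_equal(seed_count_profile(array(FALSE, c(4, 4, 2)), c(1, 1, 1)),
               data.frame(threshold = numeric(), n_seeds = integer()))
})
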