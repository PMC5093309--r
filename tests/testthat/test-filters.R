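test_that("gaussian_blur matches direct convolution within 1%", {
  set.seed(20)
  a <- array(rnorm(24 * 24 * 12, 100, 10), c(24, 24, 12))
  g <- voxel_grid(a, c(1, 1, 1))
  out <- gaussian_blur(g, 2)$data
  # direct dense separable convolution with the same reflected boundary
  kern <- function(s) {
    h <- ceiling(3.5 * s)
    k <- exp(-0.5 * (-h:h)^2 / s^2)
    k / sum(k)
  }
  refl <- function(i, n) {
    p <- 2 * n
    i <- ((i %% p) + p) %% p
    ifelse(i < n, i, p - 1 - i)
  }
  conv1 <- function(v, k) {
    h <- (length(k) - 1) / 2
    n <- length(v)
    vapply(seq_len(n), function(i) {
      idx <- refl((i - 1) + (-h:h), n) + 1
      sum(k * v[idx])
    }, numeric(1))
  }
  ref <- a
  k <- kern(2)
  for (j in 1:24) for (l in 1:12) ref[, j, l] <- conv1(ref[, j, l], k)
  for (i in 1:24) for (l in 1:12) ref[i, , l] <- conv1(ref[i, , l], k)
  for (i in 1:24) for (j in 1:24) ref[i, j, ] <- conv1(ref[i, j, ], k)
  expect_lt(max(abs(out - ref)) / max(abs(ref)), 0.01)
})

test_that("gaussian_blur respects physical units on anisotropic grids", {
  set.seed(21)
  a <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  iso <- gaussian_blur(voxel_grid(a, c(1, 1, 1)), 2)$data
  # same data on a 2 um z spacing must blur with sigma_vox = 1 on z,
  # equal to blurring the isotropic grid with sigma (2, 2, 1) voxels
  aniso <- gaussian_blur(voxel_grid(a, c(1, 1, 2)), 2)$data
  ref <- gaussian_blur(voxel_grid(a, c(1, 1, 1)), c(2, 2, 1))$data
  expect_equal(aniso, ref)
  expect_false(isTRUE(all.equal(aniso, iso)))
})

test_that("gaussian_blur preserves constants and total mass", {
  g <- voxel_grid(array(4, c(12, 12, 6)), c(1, 1, 1))
  expect_equal(gaussian_blur(g, 3)$data, g$data)
  set.seed(22)
  g2 <- voxel_grid(array(runif(12 * 12 * 6), c(12, 12, 6)), c(1, 1, 1))
  expect_equal(sum(gaussian_blur(g2, 1.5)$data), sum(g2$data),
               tolerance = 1e-8)
})

test_that("dog_filter is linear, kills constants, and validates scales", {
  set.seed(23)
  a <- array(rnorm(20 * 20 * 10, 50, 5), c(20, 20, 10))
  g <- voxel_grid(a, c(1, 1, 1))
  p <- detection_params(1, 4, 1L, 0.5)
  d1 <- dog_filter(g, p)$data
  d2 <- dog_filter(voxel_grid(3 * a, g$spacing), p)$data
  expect_equal(d2, 3 * d1, tolerance = 1e-10)
  expect_true(all(abs(dog_filter(voxel_grid(array(9, dim(a)), g$spacing),
                                 p)$data) < 1e-9))
  expect_error(dog_filter(g, list(sigma_small = 4, sigma_large = 1)),
               "sigma_small < sigma_large")
})

test_that("label_components distinguishes 6- and 26-connectivity", {
  m <- array(FALSE, c(4, 4, 2))
  m[1, 1, 1] <- TRUE
  m[2, 2, 1] <- TRUE  # diagonal neighbour
  lab26 <- label_components(m, 26L)
  lab6 <- label_components(m, 6L)
  expect_equal(max(lab26), 1L)
  expect_equal(max(lab6), 2L)
  expect_equal(sum(lab26 > 0), 2L)
})

test_that("label_components labels match a flood-fill oracle count", {
  set.seed(24)
  m <- array(runif(15 * 15 * 6) < 0.2, c(15, 15, 6))
  lab <- label_components(m, 26L)
  expect_equal(lab > 0L, m)  # support preserved
  # every component is internally connected and maximal: neighbours of a
  # component never carry a different positive label
  d <- dim(m)
  for (cl in seq_len(max(lab))) {
    idx <- which(lab == cl, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      nb <- expand.grid(i = idx[r, 1] + (-1:1), j = idx[r, 2] + (-1:1),
                        k = idx[r, 3] + (-1:1))
      nb <- nb[nb$i >= 1 & nb$i <= d[1] & nb$j >= 1 & nb$j <= d[2] &
               nb$k >= 1 & nb$k <= d[3], ]
      lnb <- lab[cbind(nb$i, nb$j, nb$k)]
      expect_true(all(lnb[lnb > 0] == cl))
    }
  }
})

test_that("distance_transform matches a brute-force oracle with anisotropy", {
  set.seed(25)
  m <- array(runif(8 * 8 * 4) < 0.6, c(8, 8, 4))
  sp <- c(0.5, 1, 2)
  dt <- distance_transform(m, sp)
  bg <- which(!m, arr.ind = TRUE)
  fg <- which(m, arr.ind = TRUE)
  skip_if(nrow(bg) == 0)
  for (r in seq_len(nrow(fg))) {
    d2 <- (sp[1] * (bg[, 1] - fg[r, 1]))^2 +
      (sp[2] * (bg[, 2] - fg[r, 2]))^2 +
      (sp[3] * (bg[, 3] - fg[r, 3]))^2
    expect_equal(dt[fg[r, 1], fg[r, 2], fg[r, 3]], sqrt(min(d2)),
                 tolerance = 1e-12)
  }
  expect_true(all(dt[!m] == 0))
})
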