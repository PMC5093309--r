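make_duct <- function(d, nduct, sig = NULL) {
  m <- array(FALSE, d)
  m[seq_len(nduct)] <- TRUE
  duct <- clonemap3d:::new_duct_model(m)
  if (!is.null(sig)) duct <- set_significant_mask(duct, sig)
  duct
}

test_that("volumetric_ratio arithmetic and error cases", {
  d <- c(25, 20, 20)  # 10,000 voxels
  duct <- make_duct(d, 10000L)
  lab <- array(0L, d)
  expect_equal(volumetric_ratio(lab, duct)$ratio, 0)
  lab[seq_len(500)] <- 1L
  q <- volumetric_ratio(lab, duct)
  expect_equal(q$ratio, 0.05)
  expect_equal(q$eyfp_volume_voxels, 500L)
  expect_equal(q$duct_volume_voxels, 10000L)
  lab[] <- 1L
  expect_equal(volumetric_ratio(lab, duct)$ratio, 1)
  empty <- make_duct(d, 0L)
  expect_error(volumetric_ratio(lab, empty), "zero")
})

test_that("volumetric_ratio supports significant-voxel denominators and regions", {
  d <- c(10, 10, 10)
  sig <- array(FALSE, d); sig[1:200] <- TRUE
  duct <- make_duct(d, 400L, sig)
  lab <- array(0L, d); lab[1:50] <- 1L
  expect_equal(volumetric_ratio(lab, duct, denominator = "significant")$ratio,
               50 / 200)
  reg <- array(FALSE, d); reg[1:100] <- TRUE
  expect_equal(volumetric_ratio(lab, duct, region_mask = reg)$ratio, 50 / 100)
  duct_nosig <- make_duct(d, 400L)
  expect_error(volumetric_ratio(lab, duct_nosig, denominator = "significant"),
               "significant_mask")
})

test_that("summarize_regions matches an oracle and flags single regions", {
  expect_equal(summarize_regions(c(0.02, 0.04, 0.06, 0.08))$mean, 0.05)
  s1 <- summarize_regions(0.3)
  expect_equal(s1$sd, 0)
  expect_true(s1$single_region)
  set.seed(70)
  r <- runif(17)
  s <- summarize_regions(r)
  expect_equal(s$mean, sum(r) / 17)
  expect_equal(s$sd, sqrt(sum((r - mean(r))^2) / 16))
  expect_error(summarize_regions(numeric()), "at least one")
})

test_that("ks_k8_distribution statistics, direction, and warnings", {
  set.seed(71)
  x <- rnorm(300)
  same <- ks_k8_distribution(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$direction, "none")
  hi <- ks_k8_distribution(rnorm(200), rnorm(200, 2))
  expect_lt(hi$p, 0.05)
  expect_equal(hi$direction, "hi-enriched")
  lo <- ks_k8_distribution(rnorm(200, 2), rnorm(200))
  expect_equal(lo$direction, "lo-enriched")
  expect_warning(ks_k8_distribution(rnorm(3), rnorm(100)), "fewer than 5")
  expect_error(ks_k8_distribution(numeric(), rnorm(5)), "nonempty")
})

test_that("min_progenitor_estimate reproduces the printed reciprocals", {
  expect_equal(min_progenitor_estimate(0.047), 1 / 0.047)
  expect_equal(clonemap3d:::floor_to_5(min_progenitor_estimate(0.047)), 20)
  expect_equal(clonemap3d:::floor_to_5(min_progenitor_estimate(0.058)), 15)
  expect_equal(min_progenitor_estimate(1), 1)
  expect_error(min_progenitor_estimate(0), "0, 1")
  # strictly decreasing in the ratio
  rs <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(vapply(rs, min_progenitor_estimate, 0)) < 0))
})

test_that("group_clones merges by surface distance with single linkage", {
  one <- group_clones(list(matrix(c(1, 1, 1), 1)), physical = TRUE)
  expect_equal(one$clone_count, 1L)
  # two regions 1500 um apart stay separate at the 1 mm default
  two <- group_clones(list(matrix(c(0, 0, 0), 1), matrix(c(1500, 0, 0), 1)),
                      physical = TRUE)
  expect_equal(two$clone_count, 2L)
  # pairwise 400, 600, 1800 um -> transitive merge into two? No: 0.4 and
  # 0.6 both merge with the middle region -> a single chain, plus none
  # else; distances 0 <-> 400 <-> 1000: construct explicitly
  three <- group_clones(list(matrix(c(0, 0, 0), 1),
                             matrix(c(400, 0, 0), 1),
                             matrix(c(1000, 0, 0), 1),
                             matrix(c(2800, 0, 0), 1)),
                        physical = TRUE)
  expect_equal(three$clone_count, 2L)
  expect_equal(three$assignments[1], three$assignments[3])
  expect_false(three$assignments[1] == three$assignments[4])
  # voxel-index input honours spacing
  vox <- group_clones(list(matrix(c(1, 1, 1), 1), matrix(c(1, 1, 301), 1)),
                      spacing = c(1, 1, 4), min_separation = 1000)
  expect_equal(vox$clone_count, 2L)
  expect_equal(group_clones(list())$clone_count, 0L)
})

test_that("group_clones equals a brute-force single-linkage oracle", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    pts <- lapply(seq_len(n), function(i)
      matrix(runif(3 * sample(1:5, 1), 0, 3000), ncol = 3))
    got <- group_clones(pts, physical = TRUE, min_separation = 800)
    # oracle: adjacency by min pairwise distance, transitive closure
    adj <- diag(n) > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dmin <- min(sqrt(outer(rowSums(pts[[i]]^2), rowSums(pts[[j]]^2), `+`) -
                       2 * pts[[i]] %*% t(pts[[j]])))
      adj[i, j] <- adj[j, i] <- dmin <= 800
    }
    reach <- adj
    for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
    comp <- match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
                  unique(apply(reach, 1, function(r)
                    paste(which(r), collapse = ","))))
    expect_equal(got$clone_count, length(unique(comp)))
    expect_equal(as.integer(factor(got$assignments)),
                 as.integer(factor(comp)))
  }
})

test_that("alveolar_occupancy counts full and partial alveoli", {
  cells <- data.frame(
    alveolus_id = c(rep(1, 20), rep(2, 20), rep(3, 10)),
    lineage = "luminal",
    labelled = c(rep(TRUE, 20), rep(TRUE, 3), rep(FALSE, 17), rep(FALSE, 10)))
  occ <- alveolar_occupancy(cells, "luminal")
  expect_equal(occ$n_full, 1L)
  expect_equal(occ$n_partial, 1L)
  # fully labelled alveolus of the other lineage is not counted
  expect_equal(alveolar_occupancy(cells, "basal")$n_full, 0L)
  # exact recovery of a constructed 10 full / 35 partial lobule
  set.seed(73)
  mk <- function(id, nfull) data.frame(
    alveolus_id = id, lineage = "luminal",
    labelled = c(rep(TRUE, nfull), rep(FALSE, 12 - nfull)))
  lob <- do.call(rbind, c(lapply(1:10, function(i) mk(i, 12)),
                          lapply(11:45, function(i) mk(i, sample(1:11, 1))),
                          lapply(46:50, function(i) mk(i, 0))))
  occ2 <- alveolar_occupancy(lob, "luminal")
  expect_equal(occ2$n_full, 10L)
  expect_equal(occ2$n_partial, 35L)
})

test_that("clone_report assembles summary fields and ratios scale-invariance", {
  regs <- list(structure(list(region_id = 1, eyfp_volume_voxels = 50,
                              duct_volume_voxels = 1000, ratio = 0.05),
                         class = "region_quantification"),
               structure(list(region_id = 2, eyfp_volume_voxels = 30,
                              duct_volume_voxels = 1000, ratio = 0.03),
                         class = "region_quantification"))
  rep <- clone_report(regs, clone_count = 2L)
  expect_equal(rep$mean_ratio, 0.04)
  expect_equal(rep$n_regions, 2L)
  expect_equal(rep$min_progenitors, 25)
  expect_equal(rep$min_progenitors_bound, 25)
  expect_equal(rep$clone_count, 2L)
})
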