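# Multiresolution (Haar-family) machinery: decimated coarse pyramid for
# duct detection, 2D per-plane detail coefficients for significant-voxel
# detection, and an orthonormal 3D transform reused by the denoiser.

# pad an array along each axis by edge replication so dims are multiples of f
pad_to_multiple <- function(a, f) {
  d <- dim(a)
  target <- ceiling(d / f) * f
  for (ax in 1:3) {
    extra <- target[ax] - dim(a)[ax]
    if (extra > 0) {
      idx <- c(seq_len(dim(a)[ax]), rep(dim(a)[ax], extra))
      a <- switch(ax,
                  a[idx, , , drop = FALSE],
                  a[, idx, , drop = FALSE],
                  a[, , idx, drop = FALSE])
    }
  }
  a
}

# mean-pool along the first axis by factor f
pool_axis1 <- function(a, f) {
  d <- dim(a)
  dim(a) <- c(f, d[1] / f, d[2], d[3])
  colMeans(a, dims = 1)
}

# decimated lowpass approximation: mean over f = (fx, fy, fz) blocks
block_reduce_mean <- function(a, f) {
  f <- as.integer(f)
  a <- pad_to_multiple(a, f)
  if (f[1] > 1) a <- pool_axis1(a, f[1])
  if (f[2] > 1) {
    a <- aperm(a, c(2, 1, 3))
    a <- pool_axis1(a, f[2])
    a <- aperm(a, c(2, 1, 3))
  }
  if (f[3] > 1) {
    a <- aperm(a, c(3, 2, 1))
    a <- pool_axis1(a, f[3])
    a <- aperm(a, c(3, 2, 1))
  }
  a
}

# nearest-neighbour block replication back to `dims`
upsample_block <- function(a, f, dims) {
  f <- as.integer(f)
  out <- a[rep(seq_len(dim(a)[1]), each = f[1]),
           rep(seq_len(dim(a)[2]), each = f[2]),
           rep(seq_len(dim(a)[3]), each = f[3]), drop = FALSE]
  out[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
}

#' Decimated coarse multiresolution approximation
#'
#' Lowpass-and-decimate pyramid of a voxel grid: each level halves the
#' lateral axes by 2x2 block averaging. Because confocal stacks are
#' axially anisotropic, the z axis is decimated at its own (usually
#' shallower) level so the physical pooling scale stays near-isotropic;
#' by default the z level is reduced by the base-2 log of the spacing
#' anisotropy, floored at zero.
#'
#' @param grid a `voxel_grid`.
#' @param coarse_level positive integer, lateral decimation level.
#' @param coarse_level_z optional z decimation level; default derived from
#'   the spacing anisotropy.
#' @return a `voxel_grid` holding the decimated approximation, with
#'   spacing scaled by the block factors.
#' @export
multiresolution_coarse <- function(grid, coarse_level, coarse_level_z = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  coarse_level <- as.integer(coarse_level)
  if (coarse_level < 1L) stop("coarse_level must be >= 1")
  if (is.null(coarse_level_z)) {
    aniso <- grid$spacing[3] / mean(grid$spacing[1:2])
    coarse_level_z <- max(coarse_level - round(log2(max(aniso, 1))), 0L)
  }
  coarse_level_z <- as.integer(coarse_level_z)
  d <- dim(grid$data)
  maxlev <- floor(log2(d))
  if (d[1] < 2^coarse_level || d[2] < 2^coarse_level)
    stop(sprintf("coarse_level %d too deep for grid %dx%dx%d (max lateral level %d)",
                 coarse_level, d[1], d[2], d[3], min(maxlev[1:2])))
  if (coarse_level_z > 0L && d[3] < 2^coarse_level_z)
    stop(sprintf("z level %d too deep for %d planes (max z level %d)",
                 coarse_level_z, d[3], maxlev[3]))
  f <- c(2^coarse_level, 2^coarse_level, 2^coarse_level_z)
  coarse <- block_reduce_mean(grid$data, f)
  voxel_grid(coarse, grid$spacing * f)
}

# --- 2D per-plane orthonormal Haar details (one level) -----------------

# returns list(LH, HL, HH) detail matrices for one image plane; the plane
# is edge-padded to even dimensions first
haar2_details <- function(p) {
  d <- dim(p)
  if (d[1] %% 2L) p <- rbind(p, p[d[1], , drop = FALSE])
  if (d[2] %% 2L) p <- cbind(p, p[, ncol(p), drop = FALSE])
  o1 <- seq(1, nrow(p), by = 2); o2 <- o1 + 1
  sL <- (p[o1, , drop = FALSE] + p[o2, , drop = FALSE]) / sqrt(2)
  sH <- (p[o1, , drop = FALSE] - p[o2, , drop = FALSE]) / sqrt(2)
  c1 <- seq(1, ncol(p), by = 2); c2 <- c1 + 1
  list(
    LH = (sL[, c1, drop = FALSE] - sL[, c2, drop = FALSE]) / sqrt(2),
    HL = (sH[, c1, drop = FALSE] + sH[, c2, drop = FALSE]) / sqrt(2),
    HH = (sH[, c1, drop = FALSE] - sH[, c2, drop = FALSE]) / sqrt(2)
  )
}

# FDR-selected detail coefficients of one plane -> logical plane marking
# every voxel covered by a surviving 2x2 coefficient support
plane_significant <- function(p, fdr_q) {
  det <- haar2_details(p)
  d <- dim(p)
  hits <- matrix(FALSE, ceiling(d[1] / 2), ceiling(d[2] / 2))
  pv <- lapply(det, function(m) {
    ctr <- m - stats::median(m)
    sc <- stats::median(abs(ctr)) / 0.6745
    if (sc <= 0) return(matrix(1, nrow(m), ncol(m)))
    matrix(2 * stats::pnorm(-abs(ctr) / sc), nrow(m), ncol(m))
  })
  adj <- stats::p.adjust(unlist(pv, use.names = FALSE), method = "BH")
  adj <- array(adj, dim = c(length(pv[[1]]), 3L))
  for (b in 1:3)
    hits <- hits | matrix(adj[, b] <= fdr_q, nrow(hits), ncol(hits))
  # expand each coefficient to its 2x2 support, crop to the plane
  out <- hits[rep(seq_len(nrow(hits)), each = 2),
              rep(seq_len(ncol(hits)), each = 2), drop = FALSE]
  out[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

# --- orthonormal 3D Haar (used by the denoiser) ------------------------

haar1d_axis1 <- function(a) {
  d <- dim(a)
  o1 <- seq(1, d[1], by = 2); o2 <- o1 + 1
  s <- (a[o1, , , drop = FALSE] + a[o2, , , drop = FALSE]) / sqrt(2)
  w <- (a[o1, , , drop = FALSE] - a[o2, , , drop = FALSE]) / sqrt(2)
  arr <- array(0, d)
  arr[seq_len(d[1] / 2), , ] <- s
  arr[(d[1] / 2 + 1):d[1], , ] <- w
  arr
}

ihaar1d_axis1 <- function(a) {
  d <- dim(a)
  h <- d[1] / 2
  s <- a[seq_len(h), , , drop = FALSE]
  w <- a[(h + 1):d[1], , , drop = FALSE]
  arr <- array(0, d)
  o1 <- seq(1, d[1], by = 2)
  arr[o1, , ] <- (s + w) / sqrt(2)
  arr[o1 + 1, , ] <- (s - w) / sqrt(2)
  arr
}

apply_axis <- function(a, ax, fun) {
  if (ax == 1) return(fun(a))
  perm <- switch(ax, NULL, c(2, 1, 3), c(3, 2, 1))
  aperm(fun(aperm(a, perm)), perm)
}

# one-level 3D Haar forward / inverse on an even-dimension array
haar3_fwd1 <- function(a) {
  for (ax in 1:3) a <- apply_axis(a, ax, haar1d_axis1)
  a
}
haar3_inv1 <- function(a) {
  for (ax in 3:1) a <- apply_axis(a, ax, ihaar1d_axis1)
  a
}
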