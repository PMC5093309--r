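# Synthetic 3D mammary stack generator: a stylized bilayered branching
# duct (outer SMA+ basal shell, inner K8+ luminal cells with hi/lo
# subpopulations), sparse EYFP-labelled clones of one founder lineage,
# embedded in autofluorescent fat-pad tissue, rendered through a simple
# forward optical model (anisotropic Gaussian PSF, depth attenuation,
# Poisson-Gaussian noise, 12-bit quantization), with full ground truth
# for every stage.

#' Simulation configuration
#'
#' @param grid_shape voxels (nx, ny, nz).
#' @param voxel_spacing um (dx, dy, dz); dz >= dx as in confocal stacks.
#' @param mode "ductal" (branching tube) or "alveolar" (spherical alveoli
#'   at terminal tips).
#' @param tree_depth number of bifurcation generations (0 = one segment).
#' @param duct_radius duct (tube) radius at the root, um.
#' @param alveolus_radius alveolus radius, um (alveolar mode).
#' @param cell_radius luminal cell radius, um.
#' @param k8hi_fraction probability that a luminal cell is K8-high;
#'   default 0.5 in ductal mode, 0.02 in alveolar mode (K8-high cells are
#'   extremely sparse in lactational alveoli).
#' @param founder_lineage lineage carrying the EYFP label ("luminal" or
#'   "basal").
#' @param target_label_fraction target labelled fraction of total cellular
#'   volume, in [0, 1].
#' @param label_pattern "clonal" (default; labels cluster along branches
#'   with per-branch dilution, as clonal progeny do) or "scattered"
#'   (labelled cells keep a minimum mutual distance, as sporadic
#'   single-cell labelling events do).
#' @param intensity_levels named mean intensities on the 0-4095 (12-bit)
#'   scale: eyfp, k8_hi, k8_lo, sma. The K8/SMA defaults are bright
#'   (antibody-amplified immunostains); the EYFP default is deliberately
#'   dim (endogenous, non-amplified fluorescence over a strong
#'   autofluorescent background, as in cleared tissue).
#' @param af_level peak tissue-autofluorescence intensity (12-bit scale).
#'   Cleared fat pad autofluoresces in every channel; the stromal
#'   background of a real stack is this structured texture, not darkness,
#'   and the robust background statistics of the analysis are estimated
#'   from it. 0 disables.
#' @param af_scale correlation length of the autofluorescence texture, um
#'   (roughly the adipocyte scale).
#' @param psf_sigma Gaussian PSF sd in um (lateral, axial).
#' @param attenuation_length depth attenuation length in um (Inf = none).
#' @param noise_gain Poisson gain (intensity units per photon; 0 disables
#'   shot noise).
#' @param noise_read_sd Gaussian read-noise sd (0 disables).
#' @param seed integer seed for geometry and labelling.
#' @param noise_seed integer seed for the optics/noise stream; defaults to
#'   `seed + 9973` so noise can be re-drawn on fixed ground truth.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(grid_shape = c(256L, 256L, 64L),
                       voxel_spacing = c(0.5, 0.5, 2),
                       mode = c("ductal", "alveolar"),
                       tree_depth = 1L,
                       duct_radius = 15,
                       alveolus_radius = 28,
                       cell_radius = 3.5,
                       k8hi_fraction = NULL,
                       founder_lineage = c("luminal", "basal"),
                       target_label_fraction = 0.05,
                       label_pattern = c("clonal", "scattered"),
                       intensity_levels = c(eyfp = 800, k8_hi = 3200,
                                            k8_lo = 2000, sma = 2600),
                       af_level = 300,
                       af_scale = 12,
                       psf_sigma = c(0.6, 1.8),
                       attenuation_length = 600,
                       noise_gain = 4,
                       noise_read_sd = 20,
                       seed = 1L,
                       noise_seed = NULL) {
  mode <- match.arg(mode)
  founder_lineage <- match.arg(founder_lineage)
  label_pattern <- match.arg(label_pattern)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("grid_shape must be three positive voxel counts")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("voxel_spacing must be three positive um values")
  if (voxel_spacing[3] < voxel_spacing[1])
    stop("dz must be >= dx (axial sampling is coarser in confocal stacks)")
  if (tree_depth < 0) stop("tree_depth must be >= 0")
  if (!(duct_radius > cell_radius && cell_radius > 0))
    stop("need duct_radius > cell_radius > 0")
  if (is.null(k8hi_fraction))
    k8hi_fraction <- if (mode == "alveolar") 0.02 else 0.5
  for (f in c(k8hi_fraction, target_label_fraction))
    if (!is.numeric(f) || f < 0 || f > 1)
      stop("fractions must lie in [0, 1]")
  need <- c("eyfp", "k8_hi", "k8_lo", "sma")
  if (!all(need %in% names(intensity_levels)))
    stop("intensity_levels must name eyfp, k8_hi, k8_lo, sma")
  if (any(intensity_levels < 0) || any(intensity_levels > 4095))
    stop("intensity levels must lie within [0, 4095]")
  if (af_level < 0 || af_level > min(intensity_levels))
    stop("af_level must lie in [0, min(intensity_levels)]")
  if (af_scale <= 0) stop("af_scale must be positive")
  if (attenuation_length <= 0) stop("attenuation_length must be positive (or Inf)")
  seed <- as.integer(seed)
  if (is.null(noise_seed)) noise_seed <- seed + 9973L
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 mode = mode, tree_depth = as.integer(tree_depth),
                 duct_radius = duct_radius, alveolus_radius = alveolus_radius,
                 cell_radius = cell_radius, k8hi_fraction = k8hi_fraction,
                 founder_lineage = founder_lineage,
                 target_label_fraction = target_label_fraction,
                 label_pattern = label_pattern,
                 intensity_levels = intensity_levels,
                 af_level = af_level, af_scale = af_scale,
                 psf_sigma = as.numeric(psf_sigma),
                 attenuation_length = attenuation_length,
                 noise_gain = noise_gain, noise_read_sd = noise_read_sd,
                 seed = seed, noise_seed = as.integer(noise_seed)),
            class = "sim_config")
}

# geometry used by both placement and fit checks: basal (myoepithelial)
# cells are thin elongated spindles hugging the duct surface
basal_semi_axes <- function(cell_radius)
  c(along = 2.5 * cell_radius, trans = 0.5 * cell_radius)

# unit vectors spanning the plane orthogonal to u
orthonormal_frame <- function(u) {
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(u = u, v = v, w = w)
}

#' Sample a branching duct skeleton
#'
#' Generates a stylized binary ductal tree: a trunk entering from the low-x
#' face that bifurcates `tree_depth` times, with segment length and radius
#' shrinking per generation, mimicking bifurcation and branching from
#' terminal end buds. Deterministic given `config$seed`.
#'
#' @param config a `sim_config` with `mode = "ductal"` (alveolar trees use
#'   the same skeleton; alveoli are attached at the tips later).
#' @return a `tree_skeleton`: `nodes` (id, x, y, z in um), `edges`
#'   (from, to, radius, generation), `root` node id.
#' @export
sample_duct_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ext <- config$grid_shape * config$voxel_spacing
  margin <- config$duct_radius + config$cell_radius
  depth <- config$tree_depth
  len_decay <- 0.75
  rad_decay <- 0.92
  usable_x <- ext[1] - 2 * margin
  min_x <- 4 * config$duct_radius * sum(len_decay^(0:depth)) * 0.5
  if (usable_x < min_x || ext[2] < 2 * margin || ext[3] < 2 * margin) {
    need <- ceiling((min_x + 2 * margin) / config$voxel_spacing[1])
    stop(sprintf(
      "tree (depth %d, duct radius %g um) cannot fit grid %s; need at least %d x %d x %d voxels at this spacing",
      depth, config$duct_radius,
      paste(config$grid_shape, collapse = "x"),
      need,
      ceiling(2 * margin / config$voxel_spacing[2]) * 2L,
      ceiling(2 * margin / config$voxel_spacing[3])))
  }
  L0 <- 0.95 * usable_x / sum((len_decay * 1.02)^(0:depth))
  nodes <- data.frame(id = 1L,
                      x = margin,
                      y = ext[2] / 2 + stats::runif(1, -0.05, 0.05) * ext[2],
                      z = ext[3] / 2)
  edges <- data.frame(from = integer(), to = integer(),
                      radius = numeric(), generation = integer())
  nextid <- 2L
  # frontier: list of (node id, direction, generation)
  frontier <- list(list(node = 1L, dir = c(1, 0, 0), gen = 0L))
  zspan <- max(ext[3] / 2 - margin, 0)
  while (length(frontier) > 0) {
    nf <- list()
    for (fr in frontier) {
      g <- fr$gen
      L <- L0 * len_decay^g
      dir <- fr$dir / sqrt(sum(fr$dir^2))
      p0 <- as.numeric(nodes[nodes$id == fr$node, c("x", "y", "z")])
      p1 <- p0 + dir * L
      # keep within bounds (reflect y/z softly, clamp)
      p1[2] <- min(max(p1[2], margin), ext[2] - margin)
      p1[3] <- min(max(p1[3], ext[3] / 2 - zspan), ext[3] / 2 + zspan)
      nodes <- rbind(nodes, data.frame(id = nextid, x = p1[1], y = p1[2],
                                       z = p1[3]))
      edges <- rbind(edges, data.frame(from = fr$node, to = nextid,
                                       radius = config$duct_radius * rad_decay^g,
                                       generation = g))
      if (g < depth) {
        theta <- stats::runif(1, 25, 40) * pi / 180
        base <- atan2(dir[2], dir[1])
        for (sgn in c(-1, 1)) {
          ang <- base + sgn * theta * stats::runif(1, 0.8, 1.2)
          tilt <- stats::runif(1, -0.08, 0.08)
          nf[[length(nf) + 1]] <- list(
            node = nextid,
            dir = c(cos(ang), sin(ang), tilt),
            gen = g + 1L)
        }
      }
      nextid <- nextid + 1L
    }
    frontier <- nf
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, root = 1L,
                 extent = ext), class = "tree_skeleton")
}

#' @export
print.tree_skeleton <- function(x, ...) {
  tips <- setdiff(x$edges$to, x$edges$from)
  cat(sprintf("<tree_skeleton> %d segments, %d terminal tips, %d nodes\n",
              nrow(x$edges), length(tips), nrow(x$nodes)))
  invisible(x)
}

# lattice points filling a disc of radius rmax with spacing s (local
# 2D); rings are anchored at the outer radius so the outermost cell ring
# always sits against the disc boundary
disc_lattice <- function(rmax, s) {
  if (rmax < 0) return(matrix(numeric(), ncol = 2))
  pts <- matrix(c(0, 0), ncol = 2)
  if (rmax >= 0.5 * s) {
    for (rho in seq(rmax, 0.5 * s, by = -s)) {
      k <- max(1L, round(2 * pi * rho / s))
      ang <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
      pts <- rbind(pts, cbind(rho * cos(ang), rho * sin(ang)))
    }
  }
  pts
}

# near-uniform points on a sphere of radius R (Fibonacci lattice)
sphere_lattice <- function(R, s) {
  n <- max(4L, round(4 * pi * R^2 / s^2))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(R * sin(phi) * cos(theta), R * sin(phi) * sin(theta), R * cos(phi))
}

#' Place epithelial cells on a duct tree
#'
#' Populates every segment with an outer shell of elongated basal cells
#' (aligned with the local duct axis) and an interior packing of
#' near-spherical luminal cells; virgin ducts are modelled as densely
#' cellular with a negligible lumen. In alveolar mode, hollow spherical
#' alveoli (basal shell + luminal lining) are attached at terminal tips.
#' Luminal cells receive a K8-high class with probability
#' `k8hi_fraction`. Cell centres keep a minimum pairwise distance of
#' 1.1 cell radii. Deterministic given `config$seed`.
#'
#' @param tree a `tree_skeleton`.
#' @param config the `sim_config` used to build the tree.
#' @return a `cell_registry` data.frame: id, lineage, x, y, z (um),
#'   ux, uy, uz (long-axis direction), ax (long semi-axis), bx (transverse
#'   semi-axis), k8_class, eyfp, parent_id, structure.
#' @export
place_cells <- function(tree, config) {
  stopifnot(inherits(tree, "tree_skeleton"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  r <- config$cell_radius
  bsa <- basal_semi_axes(r)
  min_sep <- 1.1 * r
  if (min(tree$edges$radius) < 2 * bsa["trans"] + r)
    stop(sprintf(
      "cell_radius %g um too large for duct radius %g um (basal shell + one luminal cell must fit)",
      r, min(tree$edges$radius)))
  rows <- list()
  add_cells <- function(centres, dirs, lineage, a, b, parent_id, structure_) {
    if (nrow(centres) == 0) return(NULL)
    data.frame(lineage = lineage,
               x = as.numeric(centres[, 1]), y = as.numeric(centres[, 2]),
               z = as.numeric(centres[, 3]),
               ux = as.numeric(dirs[, 1]), uy = as.numeric(dirs[, 2]),
               uz = as.numeric(dirs[, 3]),
               ax = unname(a), bx = unname(b),
               parent_id = parent_id, structure = structure_)
  }
  tips <- setdiff(tree$edges$to, tree$edges$from)
  for (e in seq_len(nrow(tree$edges))) {
    ed <- tree$edges[e, ]
    p0 <- as.numeric(tree$nodes[tree$nodes$id == ed$from, c("x", "y", "z")])
    p1 <- as.numeric(tree$nodes[tree$nodes$id == ed$to, c("x", "y", "z")])
    seg <- p1 - p0
    len <- sqrt(sum(seg^2))
    fr <- orthonormal_frame(seg)
    R <- ed$radius
    # --- luminal interior -------------------------------------------
    # luminal cells fill the tube up to the inner basal surface; they may
    # abut (but not deeply invade) the basal layer, as in the virtually
    # lumen-free virgin duct
    lum_max <- R - 2 * bsa["trans"] - 0.7 * r
    s_lat <- 1.5 * r
    disc <- disc_lattice(lum_max, s_lat)
    tpos <- seq(r, len - r, by = 1.5 * r)
    if (length(tpos) > 0 && nrow(disc) > 0) {
      grid <- expand.grid(t = tpos, i = seq_len(nrow(disc)))
      rot <- stats::runif(length(tpos), 0, 2 * pi)[match(grid$t, tpos)]
      ca <- cos(rot); sa <- sin(rot)
      lx <- disc[grid$i, 1] * ca - disc[grid$i, 2] * sa
      ly <- disc[grid$i, 1] * sa + disc[grid$i, 2] * ca
      jit <- matrix(stats::runif(3 * nrow(grid), -0.08 * r, 0.08 * r),
                    ncol = 3)
      centres <- cbind(p0[1] + grid$t * fr$u[1] + lx * fr$v[1] + ly * fr$w[1],
                       p0[2] + grid$t * fr$u[2] + lx * fr$v[2] + ly * fr$w[2],
                       p0[3] + grid$t * fr$u[3] + lx * fr$v[3] + ly * fr$w[3]) +
        jit
      dirs <- matrix(rep(fr$u, each = nrow(centres)), ncol = 3)
      rows[[length(rows) + 1]] <-
        add_cells(centres, dirs, "luminal", r, r, e, "duct")
    }
    # --- basal shell ------------------------------------------------
    rho_b <- R - bsa["trans"]
    tpos_b <- seq(bsa["along"], len - bsa["along"] * 0.5, by = 1.8 * bsa["along"])
    if (length(tpos_b) == 0) tpos_b <- len / 2
    nang <- max(3L, round(2 * pi * rho_b / (2.0 * bsa["trans"])))
    for (tb in tpos_b) {
      off <- stats::runif(1, 0, 2 * pi)
      ang <- seq(0, 2 * pi, length.out = nang + 1)[-(nang + 1)] + off
      centres <- cbind(
        p0[1] + tb * fr$u[1] + rho_b * (cos(ang) * fr$v[1] + sin(ang) * fr$w[1]),
        p0[2] + tb * fr$u[2] + rho_b * (cos(ang) * fr$v[2] + sin(ang) * fr$w[2]),
        p0[3] + tb * fr$u[3] + rho_b * (cos(ang) * fr$v[3] + sin(ang) * fr$w[3]))
      centres <- centres + matrix(stats::runif(3 * nrow(centres),
                                               -0.1 * r, 0.1 * r), ncol = 3)
      dirs <- matrix(rep(fr$u, each = nrow(centres)), ncol = 3)
      rows[[length(rows) + 1]] <-
        add_cells(centres, dirs, "basal", bsa["along"], bsa["trans"], e, "duct")
    }
    # --- alveoli at terminal tips (alveolar mode) -------------------
    if (config$mode == "alveolar" && ed$to %in% tips) {
      Ra <- config$alveolus_radius
      ctr <- p1 + fr$u * (Ra * 0.8)
      # basal shell on the sphere surface
      bs <- sphere_lattice(Ra - bsa["trans"], 2.4 * bsa["trans"])
      bc <- sweep(bs, 2, ctr, `+`)
      bdir <- t(apply(bs, 1, function(p) {
        # elongate tangentially: any unit vector orthogonal to the normal
        orthonormal_frame(p)$v
      }))
      rows[[length(rows) + 1]] <-
        add_cells(bc, bdir, "basal", bsa["along"] * 0.7, bsa["trans"],
                  ed$to, "alveolus")
      # luminal lining just inside the shell (hollow lumen)
      Rl <- Ra - 2 * bsa["trans"] - r
      if (Rl > r) {
        ls <- sphere_lattice(Rl, 1.8 * r)
        lc <- sweep(ls, 2, ctr, `+`) +
          matrix(stats::runif(3 * nrow(ls), -0.1 * r, 0.1 * r), ncol = 3)
        ldir <- matrix(rep(fr$u, each = nrow(lc)), ncol = 3)
        rows[[length(rows) + 1]] <-
          add_cells(lc, ldir, "luminal", r, r, ed$to, "alveolus")
      }
    }
  }
  reg <- do.call(rbind, rows)
  # drop cells outside the grid or violating the minimum pairwise distance
  ext <- tree$extent
  pad <- 0.5 * r
  keep <- reg$x > pad & reg$x < ext[1] - pad &
    reg$y > pad & reg$y < ext[2] - pad &
    reg$z > pad & reg$z < ext[3] - pad
  reg <- reg[keep, , drop = FALSE]
  reg <- enforce_min_separation(reg, min_sep)
  reg$id <- seq_len(nrow(reg))
  reg$k8_class <- "none"
  lum <- reg$lineage == "luminal"
  reg$k8_class[lum] <- ifelse(stats::runif(sum(lum)) < config$k8hi_fraction,
                              "hi", "lo")
  reg$eyfp <- FALSE
  rownames(reg) <- NULL
  class(reg) <- c("cell_registry", "data.frame")
  reg[, c("id", "lineage", "x", "y", "z", "ux", "uy", "uz", "ax", "bx",
          "k8_class", "eyfp", "parent_id", "structure")]
}

# greedy removal of later-placed cells closer than min_sep to an earlier one
enforce_min_separation <- function(reg, min_sep) {
  n <- nrow(reg)
  if (n < 2) return(reg)
  xyz <- as.matrix(reg[, c("x", "y", "z")])
  # spatial binning to keep the check near-linear
  bin <- floor(xyz / min_sep)
  key <- paste(bin[, 1], bin[, 2], bin[, 3])
  keep <- logical(n)
  occupied <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    ok <- TRUE
    for (bx in (bin[i, 1] - 1):(bin[i, 1] + 1)) {
      for (by in (bin[i, 2] - 1):(bin[i, 2] + 1)) {
        for (bz in (bin[i, 3] - 1):(bin[i, 3] + 1)) {
          k <- paste(bx, by, bz)
          js <- occupied[[k]]
          if (!is.null(js)) {
            d2 <- (xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
              (xyz[js, 3] - xyz[i, 3])^2
            if (any(d2 < min_sep^2)) { ok <- FALSE; break }
          }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) {
      keep[i] <- TRUE
      occupied[[key[i]]] <- c(occupied[[key[i]]], i)
    }
  }
  reg[keep, , drop = FALSE]
}

# Tissue autofluorescence texture on [0, af_level]: a smoothed Gaussian
# random field at the adipocyte scale, squashed through tanh so the
# texture is bounded and bimodal (lipid-filled vs septal regions), like
# the stromal background of a cleared fat pad. The boundedness matters
# downstream: the analysis estimates background scale robustly from this
# texture, and real backgrounds do not have Gaussian tails. Drawn from
# the geometry seed stream (it is part of the scene, not the detector).
autofluorescence_field <- function(config) {
  d <- config$grid_shape
  sp <- config$voxel_spacing
  if (config$af_level <= 0) return(array(0, d))
  # synthesize at a coarse grid for speed, then upsample and re-smooth
  f <- pmax(1L, as.integer(round(pmin(config$af_scale / (2 * sp), c(8, 8, 4)))))
  dc <- as.integer(ceiling(d / f))
  w <- array(stats::rnorm(prod(dc)), dc)
  sig_c <- config$af_scale / (2 * sp * f)
  g <- .cpp_gaussian_blur3(w, dim(w), pmax(sig_c, 0.01))
  g <- array(g, dim(w))
  full <- upsample_block(g, f, d)
  # smooth out the block-replication seams at the block scale
  full <- array(.cpp_gaussian_blur3(full, d, pmax(0.75 * f, 0.3)), d)
  full <- full / stats::sd(full)
  config$af_level * 0.5 * (1 + tanh(2 * full))
}

# analytic ellipsoid volume per cell (um^3)
cell_volumes <- function(registry) (4 / 3) * pi * registry$ax * registry$bx^2

#' Assign an EYFP-labelled clone to a cell registry
#'
#' Labels cells of the founder lineage so that the labelled fraction of
#' total cellular volume approximates `target_label_fraction`, with
#' per-branch dilution: each segment inherits a randomly attenuated
#' labelling propensity from its parent, so sibling ducts carry unequal
#' labelled densities, as expected when marked daughters mix with the
#' progeny of unmarked stem cells during branching. Deterministic given
#' `config$seed`.
#'
#' @param registry a `cell_registry` from [place_cells()].
#' @param config the `sim_config`.
#' @param tree the `tree_skeleton` (for branch-wise dilution weights).
#' @return the registry with `eyfp` set.
#' @export
assign_clone <- function(registry, config, tree = NULL) {
  stopifnot(inherits(registry, "cell_registry"))
  set.seed(config$seed + 2L)
  registry$eyfp <- FALSE
  f <- config$target_label_fraction
  if (f == 0) return(registry)
  vols <- cell_volumes(registry)
  target_vol <- f * sum(vols)
  founder <- registry$lineage == config$founder_lineage
  if (sum(vols[founder]) < target_vol)
    stop(sprintf(
      "target_label_fraction %g unreachable: founder (%s) cellular volume is only %.3g of the total",
      f, config$founder_lineage, sum(vols[founder]) / sum(vols)))
  if (identical(config$label_pattern, "scattered")) {
    # sporadic labelling events: greedy random picks keeping labelled
    # cells at least 4 cell radii apart, until the volume target
    ord <- sample(which(founder))
    xyz <- as.matrix(registry[, c("x", "y", "z")])
    sel <- integer()
    vol_acc <- 0
    for (i in ord) {
      if (length(sel) > 0) {
        d2 <- (xyz[sel, 1] - xyz[i, 1])^2 + (xyz[sel, 2] - xyz[i, 2])^2 +
          (xyz[sel, 3] - xyz[i, 3])^2
        if (min(d2) < (4 * config$cell_radius)^2) next
      }
      sel <- c(sel, i)
      vol_acc <- vol_acc + vols[i]
      if (vol_acc >= target_vol - 0.5 * vols[i]) break
    }
    registry$eyfp[sel] <- TRUE
    return(registry)
  }
  # per-segment dilution: labelling propensity decays down the tree
  seg_w <- NULL
  if (!is.null(tree)) {
    seg_w <- numeric(nrow(tree$edges))
    for (e in seq_len(nrow(tree$edges))) {
      par <- which(tree$edges$to == tree$edges$from[e])
      pw <- if (length(par) == 0) 1 else seg_w[par]
      seg_w[e] <- pw * stats::runif(1, 0.25, 1)
    }
  }
  idx <- which(founder)
  w <- if (is.null(seg_w)) rep(1, length(idx)) else {
    sw <- seg_w[registry$parent_id[idx]]
    sw[is.na(sw)] <- mean(seg_w)
    sw
  }
  # weighted random order (exponential race), fill volume to the target
  ord <- idx[order(stats::rexp(length(idx)) / w)]
  csum <- cumsum(vols[ord])
  take <- ord[csum <= target_vol + 0.5 * vols[ord]]
  registry$eyfp[take] <- TRUE
  registry
}

#' Render a multi-channel stack from a cell registry
#'
#' Forward optical model: each cell contributes its class mean intensity
#' (K8 hi/lo in luminal cells, SMA in basal cells, EYFP in labelled
#' cells) over its ellipsoid; a bounded tissue-autofluorescence texture
#' is added to every channel; channels are convolved with an anisotropic
#' Gaussian PSF, attenuated by exp(-depth / attenuation_length),
#' degraded by Poisson shot noise (gain `noise_gain`) plus Gaussian read
#' noise, and quantized to integers in [0, 4095]. The noise stream uses
#' `config$noise_seed`, independent of the geometry seed.
#'
#' @param registry a labelled `cell_registry`.
#' @param tree the `tree_skeleton`.
#' @param config the `sim_config`.
#' @return list with `stack` (a `multichannel_stack` with channels EYFP,
#'   K8, SMA) and `truth` (a `ground_truth`: tree, registry, label_map of
#'   cell ids, true_label_fraction, clean pre-noise channels, config).
#' @export
render_stack <- function(registry, tree, config) {
  stopifnot(inherits(registry, "cell_registry"), inherits(config, "sim_config"))
  d <- config$grid_shape
  sp <- config$voxel_spacing
  lev <- config$intensity_levels
  k8 <- array(0, d); sma <- array(0, d); eyfp <- array(0, d)
  label_map <- array(0L, d)
  for (i in seq_len(nrow(registry))) {
    cell <- registry[i, ]
    a <- cell$ax; b <- cell$bx
    u <- c(cell$ux, cell$uy, cell$uz)
    ctr <- c(cell$x, cell$y, cell$z)
    lo <- pmax(floor((ctr - a) / sp - 0.5) + 1L, 1L)
    hi <- pmin(ceiling((ctr + a) / sp - 0.5) + 1L, d)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    px <- (ix - 0.5) * sp[1] - ctr[1]
    py <- (iy - 0.5) * sp[2] - ctr[2]
    pz <- (iz - 0.5) * sp[3] - ctr[3]
    nx <- length(ix); ny <- length(iy); nz <- length(iz)
    X <- array(px, c(nx, ny, nz))
    Y <- array(rep(py, each = nx), c(nx, ny, nz))
    Z <- array(rep(pz, each = nx * ny), c(nx, ny, nz))
    tt <- X * u[1] + Y * u[2] + Z * u[3]
    rho2 <- pmax(X^2 + Y^2 + Z^2 - tt^2, 0)
    inside <- (tt / a)^2 + rho2 / b^2 <= 1
    if (!any(inside)) next
    sub <- function(arr) arr[ix, iy, iz, drop = FALSE]
    # cells are solid: where ellipsoids overlap, the earlier-placed cell
    # owns the voxel (fluorophore concentrations do not add up)
    lblock <- sub(label_map)
    claim <- inside & lblock == 0L
    if (!any(claim)) next
    if (cell$lineage == "luminal") {
      lvl <- if (cell$k8_class == "hi") lev[["k8_hi"]] else lev[["k8_lo"]]
      block <- sub(k8); block[claim] <- lvl
      k8[ix, iy, iz] <- block
    } else {
      block <- sub(sma); block[claim] <- lev[["sma"]]
      sma[ix, iy, iz] <- block
    }
    if (cell$eyfp) {
      block <- sub(eyfp); block[claim] <- lev[["eyfp"]]
      eyfp[ix, iy, iz] <- block
    }
    lblock[claim] <- cell$id
    label_map[ix, iy, iz] <- lblock
  }
  labelled_ids <- registry$id[registry$eyfp]
  cellular <- sum(label_map > 0L)
  true_frac <- if (cellular == 0) 0 else
    sum(label_map %in% labelled_ids) / cellular
  # broad-spectrum tissue autofluorescence underlies every channel
  set.seed(config$seed + 3L)
  af <- autofluorescence_field(config)
  k8 <- k8 + af; sma <- sma + af; eyfp <- eyfp + af
  # optics: PSF + depth attenuation (applied to the noiseless channels)
  optics <- function(arr) {
    g <- voxel_grid(arr, sp)
    if (any(config$psf_sigma > 0))
      g <- gaussian_blur(g, c(config$psf_sigma[1], config$psf_sigma[1],
                              config$psf_sigma[2]))
    if (is.finite(config$attenuation_length)) {
      att <- exp(-((seq_len(d[3]) - 0.5) * sp[3]) / config$attenuation_length)
      g$data <- sweep(g$data, 3, att, `*`)
    }
    g$data
  }
  clean <- list(EYFP = optics(eyfp), K8 = optics(k8), SMA = optics(sma))
  set.seed(config$noise_seed)
  degrade <- function(arr) {
    v <- arr
    if (config$noise_gain > 0)
      v <- stats::rpois(length(v), lambda = pmax(v, 0) / config$noise_gain) *
        config$noise_gain
    if (config$noise_read_sd > 0)
      v <- v + stats::rnorm(length(v), 0, config$noise_read_sd)
    array(pmin(pmax(round(v), 0), 4095), d)
  }
  channels <- lapply(clean, degrade)
  truth <- structure(list(tree = tree, registry = registry,
                          label_map = label_map,
                          true_label_fraction = true_frac,
                          clean_channels = clean,
                          config = config, seed = config$seed),
                     class = "ground_truth")
  list(stack = multichannel_stack(channels, sp), truth = truth)
}

#' Generate a complete synthetic stack with ground truth
#'
#' Convenience wrapper chaining [sample_duct_tree()], [place_cells()],
#' [assign_clone()] and [render_stack()].
#'
#' @param config a `sim_config`.
#' @return list(stack, truth) as in [render_stack()].
#' @export
simulate_stack <- function(config = sim_config()) {
  tree <- sample_duct_tree(config)
  reg <- place_cells(tree, config)
  reg <- assign_clone(reg, config, tree)
  render_stack(reg, tree, config)
}
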