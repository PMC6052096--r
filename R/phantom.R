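# Synthetic phantom generator.
#
# Three adjacent star-shaped structures emulate the mesiotemporal anatomy on
# a T1-like grid: an elongated, mildly bent superellipsoid (HP analogue), an
# ellipsoid adjacent to its head (AM analogue) and a flattened curved slab
# (EC analogue), embedded in a brain-analogue tissue ellipsoid over a dark
# surround. Population shape variability is a truncated low-order radial
# perturbation (the first 9 real spherical-harmonic-like basis functions on
# the sphere) plus a subject-level affine jitter; both keep every structure
# star-shaped about its center by construction. Atrophy is a uniform radial
# shrink solved numerically to a target volumetric fraction. The EC analogue
# gets a weaker intensity offset from the surrounding tissue, emulating the
# low-contrast boundary that makes the entorhinal cortex the hardest of the
# three structures.

#' Phantom specification
#'
#' @param shape grid size (voxels), default 64^3 at 1 mm isotropic.
#' @param spacing voxel size in mm.
#' @param intensities named vector of noiseless region means: structures
#'   (`HP`, `AM`, `EC`), brain `tissue` and non-brain `surround`.
#' @param noise_sd additive Gaussian noise SD.
#' @param perturb_sd total RMS of the radial perturbation field as a
#'   fraction of the local radius (spread over 9 unit-RMS basis functions).
#' @param scale_jitter subject-level per-axis uniform scale jitter
#'   (+/- fraction).
#' @param shift_jitter subject-level translation jitter (+/- mm).
#' @param atrophy named vector of target volumetric fractions in (0, 1] for
#'   atrophied structures (e.g. `c(HP = 0.7, EC = 0.85)`), or `NULL`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         intensities = c(HP = 70, AM = 70, EC = 85,
                                         tissue = 100, surround = 30),
                         noise_sd = 5, perturb_sd = 0.06,
                         scale_jitter = 0.05, shift_jitter = 2,
                         atrophy = NULL) {
  if (!is.null(atrophy) && (any(atrophy <= 0) || any(atrophy > 1)))
    stop("atrophy factors must lie in (0, 1]")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 intensities = intensities, noise_sd = noise_sd,
                 perturb_sd = perturb_sd, scale_jitter = scale_jitter,
                 shift_jitter = shift_jitter, atrophy = atrophy),
            class = "phantom_spec")
}

# Base structure geometry (world mm on the default 64 mm field of view,
# relative to the grid center). Radii are ellipsoid semi-axes; `shapefun`
# multiplies the radial function to bend/flatten while staying positive.
phantom_structures <- function() {
  list(
    HP = list(center = c(-1, -6, 1), radii = c(13, 6, 5.5),
              shapefun = function(d) 1 + 0.12 * d[, 1] * d[, 3]),
    AM = list(center = c(-1, 7, 2), radii = c(6.5, 6, 5.5),
              shapefun = function(d) rep(1, nrow(d))),
    EC = list(center = c(-1, -4, -12), radii = c(11, 7.5, 3.5),
              shapefun = function(d) 1 + 0.15 * (d[, 1]^2 - 0.5))
  )
}

# First 9 real spherical-harmonic-like basis functions at unit directions,
# normalized to unit RMS over the sphere so that coefficients with SD
# perturb_sd / 3 give a radial perturbation field of total RMS perturb_sd.
sh_basis9 <- function(d) {
  cbind(1,
        sqrt(3) * d[, 1], sqrt(3) * d[, 2], sqrt(3) * d[, 3],
        sqrt(15) * d[, 1] * d[, 2], sqrt(15) * d[, 2] * d[, 3],
        sqrt(15) * d[, 3] * d[, 1],
        sqrt(15) / 2 * (d[, 1]^2 - d[, 2]^2),
        sqrt(5) / 2 * (3 * d[, 3]^2 - 1))
}

# Radial function of one perturbed structure at unit directions (mm).
# `scale` is the per-axis subject scale jitter (length 3), applied to the
# ellipsoid semi-axes.
structure_radius <- function(geom, coef, scale, dirs) {
  radii <- geom$radii * scale
  r_ell <- 1 / sqrt((dirs[, 1] / radii[1])^2 +
                    (dirs[, 2] / radii[2])^2 +
                    (dirs[, 3] / radii[3])^2)
  pert <- 1 + as.vector(sh_basis9(dirs) %*% coef)
  pert <- pmin(pmax(pert, 0.75), 1.25)
  r_ell * geom$shapefun(dirs) * pert
}

# Rasterize one structure: TRUE for voxel centers with |p - c| < R(dir).
rasterize_structure <- function(geom, coef, scale, shrink, center_mm,
                                shape, spacing) {
  rmax <- max(geom$radii * scale) * 1.5 * shrink
  lo <- pmax(floor((center_mm - rmax) / spacing), 0)
  hi <- pmin(ceiling((center_mm + rmax) / spacing), shape - 1)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = gx * spacing[1], y = gy * spacing[2],
                             z = gz * spacing[3]))
  off <- sweep(g, 2, center_mm)
  r <- sqrt(rowSums(off^2))
  inside <- r < 1e-9
  nz <- r >= 1e-9
  dirs <- off[nz, , drop = FALSE] / r[nz]
  inside[nz] <- r[nz] < structure_radius(geom, coef, scale, dirs) * shrink
  out <- array(FALSE, shape)
  out[lo[1]:hi[1] + 1, lo[2]:hi[2] + 1, lo[3]:hi[3] + 1] <-
    array(inside, hi - lo + 1)
  out
}

# Uniform radial shrink hitting a target voxel-count fraction (secant on the
# rasterized count; no RNG).
solve_shrink <- function(geom, coef, scale, center_mm, shape, spacing,
                         factor) {
  count_at <- function(s)
    sum(rasterize_structure(geom, coef, scale, s, center_mm, shape, spacing))
  n0 <- count_at(1)
  target <- factor * n0
  s1 <- factor^(1 / 3); s0 <- s1 * 0.95
  f0 <- count_at(s0) - target; f1 <- count_at(s1) - target
  for (it in 1:8) {
    if (abs(f1) <= 0.01 * target) break
    if (abs(f1 - f0) < 1e-9) break
    s2 <- s1 - f1 * (s1 - s0) / (f1 - f0)
    s2 <- min(max(s2, 0.3), 1.2)
    s0 <- s1; f0 <- f1
    s1 <- s2; f1 <- count_at(s1) - target
  }
  s1
}

# Quick star-shape validation on the rasterized label: every level-3
# icosphere ray from the foreground centroid must cross 0.5 exactly once.
star_shaped_ok <- function(fg, affine, spacing) {
  idx <- which(fg, arr.ind = TRUE) - 1L
  center <- colMeans(idx) * spacing
  ind <- volume3d(array(as.numeric(fg), dim(fg)), affine)
  dirs <- icosphere(3)$vertices
  ts <- seq(0.5, max(dim(fg) * spacing), by = 0.5)
  pts <- dirs[rep(seq_len(nrow(dirs)), each = length(ts)), , drop = FALSE] *
    rep(ts, nrow(dirs)) +
    matrix(center, nrow(dirs) * length(ts), 3, byrow = TRUE)
  vals <- matrix(trilinear_sample(ind, pts, fill = 0) >= 0.5,
                 nrow = length(ts))
  crossings <- colSums(vals[-nrow(vals), , drop = FALSE] &
                       !vals[-1, , drop = FALSE])
  all(crossings == 1) && all(vals[1, ])
}

#' Generate one synthetic phantom subject
#'
#' Deterministic for a fixed seed: identical seeds give bit-identical
#' volumes, labels and surfaces. If the drawn shape variability makes the
#' structures overlap or breaks star-shapedness, the draw is rejected and
#' regenerated (up to 10 attempts on one seeded RNG stream).
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @param surface_level correspondence sampling level (default 4).
#' @return List with `volume` (raw intensities), `label`, `surface`,
#'   `brain_mask` and a `meta` list (jitter, shrink factors, attempt count).
#' @export
make_phantom <- function(spec, seed, surface_level = 4) {
  set.seed(seed)
  shape <- spec$shape; spacing <- spec$spacing
  affine <- diag(c(spacing, 1))
  geoms <- phantom_structures()
  fov_center <- (shape - 1) * spacing / 2

  for (attempt in 1:10) {
    scale <- 1 + runif(3, -spec$scale_jitter, spec$scale_jitter)
    shift <- runif(3, -spec$shift_jitter, spec$shift_jitter)
    coefs <- lapply(geoms, function(g)
      rnorm(9, 0, spec$perturb_sd / 3))
    centers <- lapply(geoms, function(g)
      fov_center + g$center * scale + shift)
    shrinks <- stats::setNames(rep(1, 3), names(geoms))
    for (snm in names(spec$atrophy))
      shrinks[snm] <- solve_shrink(geoms[[snm]], coefs[[snm]], scale,
                                   centers[[snm]], shape, spacing,
                                   spec$atrophy[[snm]])
    masks <- lapply(names(geoms), function(snm)
      rasterize_structure(geoms[[snm]], coefs[[snm]], scale, shrinks[snm],
                          centers[[snm]], shape, spacing))
    overlap <- (masks[[1]] & masks[[2]]) | (masks[[1]] & masks[[3]]) |
      (masks[[2]] & masks[[3]])
    if (any(overlap)) next
    ok <- TRUE
    for (mk in masks)
      if (!star_shaped_ok(mk, affine, spacing)) { ok <- FALSE; break }
    if (!ok) next

    lab <- array(0L, shape)
    for (s in 1:3) lab[masks[[s]]] <- s
    label <- label_volume(lab, affine)

    # brain-analogue ellipsoid
    g <- as.matrix(expand.grid(x = (0:(shape[1] - 1)) * spacing[1],
                               y = (0:(shape[2] - 1)) * spacing[2],
                               z = (0:(shape[3] - 1)) * spacing[3]))
    off <- sweep(g, 2, fov_center)
    brain <- array(rowSums((off / (min(fov_center) * 0.88))^2) < 1, shape)

    ints <- spec$intensities
    vol <- array(ints["surround"], shape)
    vol[brain] <- ints["tissue"]
    for (s in 1:3) vol[masks[[s]]] <- ints[names(geoms)[s]]
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(prod(shape), 0, spec$noise_sd), shape)
    volume <- volume3d(vol, affine)
    surface <- label_to_mtl_surface(label, level = surface_level)
    return(list(volume = volume, label = label, surface = surface,
                brain_mask = binary_mask(brain, affine),
                meta = list(seed = seed, attempt = attempt, scale = scale,
                            shift = shift, shrink = shrinks,
                            coefs = coefs)))
  }
  stop("star-shape/overlap validation failed after 10 attempts (seed ",
       seed, ")")
}
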