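# Boundary-weighted non-linear registration of a template to the test image.
#
# The deformation is a control-lattice free-form model: a regular grid of 3D
# displacement vectors (mm) over the test volume's bounding box, interpolated
# trilinearly, optimized coarse-to-fine. The registration objective combines
# the masked intensity correlation O_vol,reg with a surface term O_surf,reg
# (correlation between boundary-contrast RI features on the true template
# surface and on the surface deformed along with the field) minus a
# smoothness penalty:
#     maximize  O_vol,reg + w_surf_reg * O_surf,reg - lambda * O_smooth.
# Each lattice node's three displacement components are optimized by
# derivative-free Nelder-Mead with all other nodes frozen, sweeping nodes in
# deterministic raster order; only improving moves are accepted, so the
# objective is monotone across sweeps and levels.

#' Registration configuration
#'
#' @param w_surf_reg weight of the surface feature term (default 1.1).
#' @param lambda smoothness weight (default 0.1).
#' @param schedule lattice spacings in mm, coarse to fine; each level must
#'   halve the previous spacing so that the final field composes exactly
#'   onto the finest lattice (default `c(8, 4)`).
#' @param nm_iters Nelder-Mead objective evaluations per node (default 60).
#' @param sweeps maximum sweeps per level (default 3; converged levels stop
#'   early via `tol`; the hybrid surface features refresh once per sweep,
#'   so raising this can squeeze a little more out of the surface term at
#'   proportional cost).
#' @param tol convergence tolerance on the sweep-to-sweep objective gain.
#' @param cap_factor per-level displacement cap as a fraction of the lattice
#'   spacing (default 0.4; keeps every level's increment locally invertible,
#'   and the default two-level total gradient bound at 0.8 < 1).
#' @param refresh_moves accepted node moves between mid-sweep refreshes of
#'   the deformed-surface indicator and feature caches (0 = refresh only
#'   between sweeps); bounds the staleness of the frozen boundary within a
#'   sweep.
#' @param surf_level icosphere prefix level used for the registration
#'   surface term (default 3, 162 vertices per structure).
#' @param ri_radius spherical neighborhood radius (mm) of the registration
#'   RI feature (default 5, the middle of the three feature radii).
#' @return A `registration_config` list.
#' @export
registration_config <- function(w_surf_reg = 1.1, lambda = 0.1,
                                schedule = c(8, 4), nm_iters = 60,
                                sweeps = 3, tol = 1e-4, cap_factor = 0.4,
                                refresh_moves = 0, surf_level = 3,
                                ri_radius = 5) {
  stopifnot(lambda >= 0, all(diff(schedule) < 0) || length(schedule) == 1)
  if (length(schedule) > 1 &&
      max(abs(schedule[-1] * 2 - schedule[-length(schedule)])) > 1e-9)
    stop("each lattice spacing must halve the previous one")
  structure(list(w_surf_reg = w_surf_reg, lambda = lambda,
                 schedule = schedule, nm_iters = as.integer(nm_iters),
                 sweeps = as.integer(sweeps), tol = tol,
                 cap_factor = cap_factor,
                 refresh_moves = as.integer(refresh_moves),
                 surf_level = as.integer(surf_level),
                 ri_radius = ri_radius),
            class = "registration_config")
}

#' Deformation field on a control lattice
#'
#' Displacements (mm) of the backward map live on a regular lattice over the
#' volume bounding box and are interpolated trilinearly; a test-space point
#' `x` samples the template at `x + d(x)`.
#'
#' @param lattice `nx x ny x nz x 3` array of node displacements in mm.
#' @param origin world-mm position of lattice node (0,0,0).
#' @param spacing lattice spacing in mm.
#' @param cap total displacement bound carried by the field (mm).
#' @return A `deformation_field`.
#' @export
deformation_field <- function(lattice, origin, spacing, cap = Inf) {
  stopifnot(length(dim(lattice)) == 4L, dim(lattice)[4] == 3L)
  structure(list(lattice = lattice, origin = origin, spacing = spacing,
                 cap = cap), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(apply(x$lattice^2, 1:3, sum))
  cat(sprintf("<deformation_field> %s lattice @ %g mm, max |d| = %.3f mm\n",
              paste(dim(x$lattice)[1:3], collapse = "x"), x$spacing,
              max(mag)))
  invisible(x)
}

zero_field_like <- function(test, spacing) {
  org <- grid_origin(test) - spacing
  ext <- (dim(test$data) - 1) * grid_spacing(test) + 2 * spacing
  n <- ceiling(ext / spacing) + 1
  deformation_field(array(0, c(n, 3)), org, spacing, cap = 0)
}

#' Evaluate a deformation field at world-mm points
#'
#' @param field a `deformation_field`.
#' @param pts n x 3 matrix of world-mm points (clamped to the lattice hull).
#' @return n x 3 matrix of displacements in mm.
#' @export
field_displacement <- function(field, pts) {
  pts <- matrix(pts, ncol = 3)
  ld <- dim(field$lattice)[1:3]
  u <- sweep(pts, 2, field$origin) / field$spacing
  u <- pmin(pmax(u, 0), matrix(ld - 1, nrow(pts), 3, byrow = TRUE))
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3)
    out[, c] <- cpp_trilinear(as.vector(field$lattice[, , , c]), ld, u, 0)
  out
}

#' Masked intensity correlation (registration volume term)
#'
#' @param warped_template,test `volume3d` objects on the same grid.
#' @param mask the registration `binary_mask` (library label union dilated
#'   5 times).
#' @return Pearson correlation of the masked intensities.
#' @export
o_vol_reg <- function(warped_template, test, mask) {
  a <- warped_template$data[mask$data]
  b <- test$data[mask$data]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    stop("constant masked region")
  stats::cor(a, b)
}

#' Surface feature correlation (registration surface term)
#'
#' Pearson correlation across vertices between the boundary-contrast RI
#' features on the true template surface and on the deformed surface over
#' the test image.
#'
#' @param f_t,f_s per-vertex RI vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
o_surf_reg <- function(f_t, f_s) {
  if (length(f_t) != length(f_s)) stop("feature vectors differ in length")
  if (stats::sd(f_t) < 1e-12 || stats::sd(f_s) < 1e-12)
    stop("zero variance in surface features")
  stats::cor(f_t, f_s)
}

#' Smoothness penalty of a deformation field
#'
#' Mean over lattice nodes of the squared discrete Laplacian of the three
#' displacement components (zero for any globally affine displacement).
#'
#' @param field a `deformation_field`.
#' @return Non-negative scalar.
#' @export
smoothness_penalty <- function(field) {
  lat <- field$lattice
  n <- dim(lat)[1:3]
  tot <- 0
  for (c in 1:3) {
    x <- lat[, , , c]
    l <- array(0, n)
    l[-1, , ] <- l[-1, , ] + x[-n[1], , ] - x[-1, , ]
    l[-n[1], , ] <- l[-n[1], , ] + x[-1, , ] - x[-n[1], , ]
    l[, -1, ] <- l[, -1, ] + x[, -n[2], ] - x[, -1, ]
    l[, -n[2], ] <- l[, -n[2], ] + x[, -1, ] - x[, -n[2], ]
    l[, , -1] <- l[, , -1] + x[, , -n[3]] - x[, , -1]
    l[, , -n[3]] <- l[, , -n[3]] + x[, , -1] - x[, , -n[3]]
    tot <- tot + sum(l^2)
  }
  tot / prod(n)
}

# Area-weighted outward vertex normals of a triangle mesh.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- rowsum_accumulate(fn, f, nrow(v))
  vn / pmax(sqrt(rowSums(vn^2)), 1e-12)
}

rowsum_accumulate <- function(fn, f, nv) {
  vn <- matrix(0, nv, 3)
  for (corner in 1:3) {
    rs <- rowsum(fn, f[, corner])
    idx <- as.integer(rownames(rs))
    vn[idx, ] <- vn[idx, ] + rs
  }
  vn
}

# Registration surface sampling: prefix of each structure mesh at
# `surf_level` (the level-l icosphere faces close the prefix into a valid
# coarse mesh), with per-vertex structure bits and per-structure face lists
# (0-based, global vertex indexing).
registration_surface <- function(template, cfg) {
  m_lvl <- icosphere_count(cfg$surf_level)
  ico_faces <- icosphere(cfg$surf_level)$faces
  verts <- NULL; faces <- list(); vbit <- integer(0)
  for (s in 1:3) {
    mesh <- template$surface$meshes[[s]]
    if (nrow(mesh$vertices) < m_lvl)
      stop("correspondence sampling is coarser than surf_level")
    verts <- rbind(verts, mesh$vertices[seq_len(m_lvl), , drop = FALSE])
    faces[[s]] <- ico_faces - 1L + (s - 1L) * m_lvl
    vbit <- c(vbit, rep(bit_of(s), m_lvl))
  }
  list(verts = verts, faces = faces, vbit = vbit, m = m_lvl)
}

# Template-side registration RI: IR/OR split by the voxelized registration
# surface on the template's own grid.
registration_true_ri <- function(template, srf, ri_off, cfg) {
  vol <- template$volume
  dims <- dim(vol$data)
  bits <- NULL
  for (s in 1:3) {
    vs <- world_to_voxel(vol, srf$verts[(s - 1) * srf$m + seq_len(srf$m), ,
                                        drop = FALSE])
    bits <- cpp_voxelize(vs, icosphere(cfg$surf_level)$faces - 1L, dims,
                         bit = bit_of(s), mask_ = bits)
  }
  cpp_indicator_ri(as.vector(vol$data), dims, grid_spacing(vol),
                   grid_origin(vol), srf$verts, bits, srf$vbit, ri_off,
                   cfg$ri_radius, 0)
}

# Registration-time RI sphere: checkerboard-decimated voxel offsets (every
# other voxel, spatially unbiased). Halves the cost of the per-candidate
# feature refresh; the same decimated set is used on the template and the
# test side, so the correlation compares like with like. Full spheres are
# used everywhere outside the registration inner loop.
ri_offsets_for <- function(spacing, radius) {
  off <- sphere_offsets(radius, spacing)
  off[rowSums(off) %% 2L == 0L, , drop = FALSE]
}

#' Hybrid non-linear registration of a template to a test image
#'
#' @param template a [make_template()] object (its volume and surface drive
#'   the registration).
#' @param test the test `volume3d`.
#' @param mask the registration `binary_mask` (library label union dilated 5
#'   times; see [template_library()]).
#' @param cfg a [registration_config()].
#' @return A `deformation_field` (single composed lattice at the finest
#'   schedule spacing) with attributes `objective` (final hybrid objective)
#'   and `trace` (per-level objective traces).
#' @export
register_hybrid <- function(template, test, mask, cfg = registration_config()) {
  assert_axis_aligned(test)
  if (!same_geometry(template$volume, test)) stop("template/test geometry mismatch")
  mask_idx <- which(mask$data) - 1L
  if (length(mask_idx) == 0) stop("no masked overlap between template and test")
  spacing <- grid_spacing(test)
  origin <- grid_origin(test)

  srf <- registration_surface(template, cfg)
  ri_off <- ri_offsets_for(spacing, cfg$ri_radius)
  f_t <- registration_true_ri(template, srf, ri_off, cfg)

  idx3 <- arrayInd(mask_idx + 1L, dim(test$data)) - 1L
  xm <- voxel_to_world(test, idx3)

  fields <- list()
  prev_vol <- matrix(0, length(mask_idx), 3)
  prev_srf <- matrix(0, nrow(srf$verts), 3)
  traces <- list()
  obj <- NA_real_
  for (li in seq_along(cfg$schedule)) {
    sp <- cfg$schedule[li]
    if (li == 1) {
      f0 <- zero_field_like(test, sp)
    } else {
      # nested refinement: same origin, spacing halved, node count doubled
      prev <- fields[[li - 1]]
      n_prev <- dim(prev$lattice)[1:3]
      f0 <- deformation_field(array(0, c(2 * (n_prev - 1) + 1, 3)),
                              prev$origin, sp, cap = 0)
    }
    ld <- dim(f0$lattice)[1:3]
    res <- cpp_register_level(
      as.vector(template$volume$data), as.vector(test$data), dim(test$data),
      spacing, origin, mask_idx, prev_vol,
      matrix(0, prod(ld), 3), ld, f0$origin, sp,
      cap = cfg$cap_factor * sp, lambda = cfg$lambda,
      w_surf = cfg$w_surf_reg, sverts = srf$verts, sfaces = srf$faces,
      svstruct = srf$vbit,
      prev_disp_surf = prev_srf, F_T = f_t, ri_offsets = ri_off,
      ri_radius = cfg$ri_radius, nm_maxit = cfg$nm_iters,
      sweeps = cfg$sweeps, tol = cfg$tol,
      refresh_moves = cfg$refresh_moves, fill = 0)
    lat <- array(res$lattice, c(ld, 3))
    fields[[li]] <- deformation_field(lat, f0$origin, sp,
                                      cap = cfg$cap_factor * sp)
    traces[[li]] <- res$trace
    obj <- res$objective
    prev_vol <- prev_vol + field_displacement(fields[[li]], xm)
    prev_srf <- prev_srf + field_displacement(fields[[li]], srf$verts)
  }

  # compose all levels exactly onto the finest lattice (nested + aligned)
  fin <- fields[[length(fields)]]
  node_idx <- as.matrix(expand.grid(i = seq_len(dim(fin$lattice)[1]) - 1,
                                    j = seq_len(dim(fin$lattice)[2]) - 1,
                                    k = seq_len(dim(fin$lattice)[3]) - 1))
  node_pos <- sweep(node_idx * fin$spacing, 2, fin$origin, `+`)
  total <- matrix(0, nrow(node_pos), 3)
  for (f in fields) total <- total + field_displacement(f, node_pos)
  lat_tot <- array(0, dim(fin$lattice))
  for (c in 1:3)
    lat_tot[, , , c] <- array(total[, c], dim(fin$lattice)[1:3])
  out <- deformation_field(lat_tot, fin$origin, fin$spacing,
                           cap = cfg$cap_factor * sum(cfg$schedule))
  attr(out, "objective") <- obj
  attr(out, "trace") <- traces
  out
}

#' Warp a volume with a deformation field (backward map)
#'
#' The test-space voxel center `x` samples the template at `x + d(x)`;
#' a zero field reproduces the input exactly.
#'
#' @param field a `deformation_field`.
#' @param vol the template `volume3d` or `label_volume` to resample.
#' @param geometry output grid (defaults to `vol`'s grid).
#' @return The resampled volume (labels use nearest-neighbour sampling).
#' @export
apply_to_volume <- function(field, vol, geometry = vol) {
  dims <- dim(geometry$data)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                               j = seq_len(dims[2]) - 1,
                               k = seq_len(dims[3]) - 1))
  x <- voxel_to_world(geometry, idx)
  y <- x + field_displacement(field, x)
  vx <- world_to_voxel(vol, y)
  if (inherits(vol, "label_volume")) {
    vals <- numeric(nrow(vx))
    rx <- round(vx)
    inb <- rx[, 1] >= 0 & rx[, 2] >= 0 & rx[, 3] >= 0 &
      rx[, 1] < dims[1] & rx[, 2] < dims[2] & rx[, 3] < dims[3]
    lin <- rx[inb, 1] + dims[1] * (rx[inb, 2] + dims[2] * rx[inb, 3]) + 1
    vals[inb] <- vol$data[lin]
    label_volume(array(as.integer(vals), dims), geometry$affine)
  } else {
    vals <- cpp_trilinear(as.vector(vol$data), dim(vol$data), vx, 0)
    volume3d(array(vals, dims), geometry$affine)
  }
}

#' Carry a surface along a deformation field (forward map)
#'
#' The forward map is the fixed-point inversion of the backward field at
#' each vertex (`x = y - d(x)`, tolerance 0.01 mm, at most 20 iterations);
#' vertices where the iteration does not converge keep the backward-map
#' estimate `y - d(y)` and are reported via a warning.
#'
#' @param field a `deformation_field`.
#' @param surface a `corresponded_surface` (template space).
#' @return The deformed `corresponded_surface`.
#' @export
apply_to_surface <- function(field, surface) {
  y <- surface_vertices(surface)
  x <- y - field_displacement(field, y)
  converged <- rep(FALSE, nrow(y))
  for (it in seq_len(20)) {
    xn <- y - field_displacement(field, x)
    delta <- sqrt(rowSums((xn - x)^2))
    x <- xn
    converged <- delta < 0.01
    if (all(converged)) break
  }
  if (!all(converged))
    warning(sum(!converged), " vertices did not converge in field inversion; ",
            "keeping last fixed-point estimate")
  surface_with_vertices(surface, x)
}

#' Serialize a deformation field (NIfTI displacement image + JSON header)
#'
#' The control lattice is written as a 4D NIfTI image (three displacement
#' components, mm) with a JSON sidecar recording the lattice origin, spacing
#' and displacement cap.
#'
#' @param field a `deformation_field`.
#' @param path output path without extension (writes `<path>.nii.gz` and
#'   `<path>.json`).
#' @return `path` (write) or a `deformation_field` (read).
#' @export
write_deformation_field <- function(field, path) {
  img <- RNifti::asNifti(field$lattice)
  RNifti::writeNifti(img, paste0(path, ".nii.gz"), datatype = "double")
  jsonlite::write_json(list(origin = field$origin, spacing = field$spacing,
                            cap = field$cap),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_deformation_field
#' @export
read_deformation_field <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  deformation_field(array(as.vector(img), dim(img)), meta$origin,
                    meta$spacing, cap = meta$cap)
}
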