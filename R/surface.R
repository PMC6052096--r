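# Surface <-> label conversion via radial icosphere parameterization.
#
# Structures are assumed star-shaped about their centroid (guaranteed by the
# synthetic generator): every ray from the centroid crosses the boundary
# exactly once, so sampling the boundary along the shared icosphere
# directions yields a vertex-wise corresponded mesh by construction.

#' Convert a labelled structure to a corresponded surface mesh
#'
#' For each direction of the level-`level` icosphere, the vertex is placed at
#' `centroid + r(direction) * direction` where `r` is the last inside-to-
#' outside 0.5-crossing of the trilinearly interpolated binary indicator
#' along the ray (sub-voxel boundary position).
#'
#' @param label a `label_volume`.
#' @param structure structure name (`"HP"`, `"AM"`, `"EC"`) or code (1-3).
#' @param level icosphere subdivision level of the correspondence sampling
#'   (default 4, 642 vertices per structure).
#' @param step ray sampling step in mm.
#' @return A list with the `triangle_mesh` (`mesh`), the unit `directions`
#'   matrix, and the parameterization `center` (world mm) — the mesh plus its
#'   spherical parameterization.
#' @export
label_to_surface <- function(label, structure, level = 4, step = 0.25) {
  assert_axis_aligned(label)
  code <- as_structure_code(structure)
  fg <- label$data == code
  if (!any(fg)) stop("empty structure: ", structure)
  if (!single_component_6(fg))
    stop("structure ", structure,
         " is not a single 6-connected component")
  idx <- which(fg, arr.ind = TRUE) - 1L
  center <- colMeans(voxel_to_world(label, idx))
  ico <- icosphere(level)
  dirs <- ico$vertices
  ind <- volume3d(array(as.numeric(fg), dim(fg)), label$affine)
  # max radius: to the bounding box corner
  ext <- dim(label$data) * grid_spacing(label)
  rmax <- sqrt(sum(pmax(center - grid_origin(label),
                        grid_origin(label) + ext - center)^2))
  ts <- seq(step, rmax, by = step)
  pts <- dirs[rep(seq_len(nrow(dirs)), each = length(ts)), , drop = FALSE] *
    rep(ts, nrow(dirs)) + matrix(center, nrow(dirs) * length(ts), 3, byrow = TRUE)
  vals <- matrix(trilinear_sample(ind, pts, fill = 0), nrow = length(ts))
  radii <- vapply(seq_len(nrow(dirs)), function(d) {
    v <- vals[, d]
    above <- v >= 0.5
    cross <- which(above[-length(v)] & !above[-1])
    if (length(cross) == 0) {
      if (!above[1])
        stop("ray with no inside samples: structure not star-shaped ",
             "about its centroid")
      stop("ray never leaves the structure: grid too small")
    }
    i <- cross[length(cross)]  # last inside -> outside crossing
    ts[i] + (v[i] - 0.5) / (v[i] - v[i + 1]) * step
  }, numeric(1))
  verts <- dirs * radii + matrix(center, nrow(dirs), 3, byrow = TRUE)
  id <- names(structure_codes)[code]
  list(mesh = triangle_mesh(verts, ico$faces, id),
       directions = dirs, center = center)
}

single_component_6 <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  seed <- which(fg)[1]
  queue <- seed
  lab[seed] <- 1L
  nx <- d[1]; nxy <- d[1] * d[2]
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    for (off in c(-1L, 1L, -nx, nx, -nxy, nxy)) {
      nb <- cur + off
      ok <- nb >= 1L & nb <= length(fg)
      # guard x-wrap for +/-1 and y-wrap for +/-nx
      if (off == -1L) ok <- ok & ((cur - 1L) %% nx != 0L)
      if (off == 1L) ok <- ok & (cur %% nx != 0L)
      if (off == -nx) ok <- ok & (((cur - 1L) %/% nx) %% d[2] != 0L)
      if (off == nx) ok <- ok & (((cur - 1L) %/% nx) %% d[2] != d[2] - 1L)
      nb <- nb[ok]
      nb <- nb[fg[nb] & lab[nb] == 0L]
      lab[nb] <- 1L
      queue <- c(queue, nb)
    }
    queue <- unique(queue)
  }
  sum(lab == 1L) == sum(fg)
}

#' Build a full corresponded MTL surface from a label volume
#'
#' Runs [label_to_surface()] for HP, AM and EC and concatenates the results.
#'
#' @inheritParams label_to_surface
#' @return A `corresponded_surface` with parameterization centers.
#' @export
label_to_mtl_surface <- function(label, level = 4, step = 0.25) {
  parts <- lapply(c("HP", "AM", "EC"), function(s)
    label_to_surface(label, s, level = level, step = step))
  concat_surface(lapply(parts, `[[`, "mesh"),
                 centers = do.call(rbind, lapply(parts, `[[`, "center")))
}

# Per-structure inside-bit indicator (bit 1 = HP, 2 = AM, 4 = EC) for the
# voxel grid of `geometry`. Used as the boundary definition for estimated
# features and for label synthesis.
voxelize_surface_bits <- function(surface, geometry) {
  assert_axis_aligned(geometry)
  dims <- dim(geometry$data)
  bits <- NULL
  for (s in 1:3) {
    m <- surface$meshes[[s]]
    vx <- world_to_voxel(geometry, m$vertices)
    bits <- cpp_voxelize(vx, m$faces - 1L, dims, bit = bit_of(s), mask_ = bits)
  }
  bits
}

bit_of <- function(s) as.integer(2^(s - 1))

#' Rasterize a corresponded surface into a label volume
#'
#' A voxel center strictly inside exactly one structure mesh receives that
#' structure's code (inside-ness by scanline ray parity). A center inside two
#' or more meshes is resolved by the nearest-surface rule (smallest unsigned
#' distance to a mesh boundary wins; ties go to the lowest structure code).
#'
#' @param surface a `corresponded_surface` with closed meshes.
#' @param geometry a `volume3d` (or label) defining the output grid.
#' @return A `label_volume` on `geometry`'s grid.
#' @export
surface_to_label <- function(surface, geometry) {
  for (m in surface$meshes) check_mesh(m)
  bits <- voxelize_surface_bits(surface, geometry)
  out <- integer(length(bits))
  for (s in 1:3) out[bits == bit_of(s)] <- s
  multi <- which(bits %in% c(3L, 5L, 6L, 7L))
  if (length(multi)) {
    dims <- dim(geometry$data)
    idx <- arrayInd(multi, dims) - 1L
    pts <- voxel_to_world(geometry, idx)
    dist <- matrix(Inf, length(multi), 3)
    for (s in 1:3) {
      has <- bitwAnd(bits[multi], bit_of(s)) != 0L
      if (!any(has)) next
      m <- surface$meshes[[s]]
      dist[has, s] <- cpp_mesh_dist(pts[has, , drop = FALSE],
                                    m$vertices, m$faces - 1L)
    }
    out[multi] <- max.col(-dist, ties.method = "first")
  }
  label_volume(array(out, dim(geometry$data)), geometry$affine)
}
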