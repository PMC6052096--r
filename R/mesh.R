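#' Triangle mesh
#'
#' @param vertices V x 3 matrix of world-mm coordinates.
#' @param faces F x 3 matrix of 1-based vertex indices with consistent
#'   outward orientation.
#' @param structure_id one of `"HP"`, `"AM"`, `"EC"` (or `NA` for generic
#'   meshes such as the unit icosphere).
#' @return A `triangle_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces, structure_id = NA_character_) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 structure_id = structure_id),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh%s> %d vertices, %d faces\n",
              if (is.na(x$structure_id)) "" else paste0(" ", x$structure_id),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Vertex count of an icosahedron subdivision level
#'
#' The nested sampling sequence `m(l) = 10 * 4^(l-1) + 2`:
#' 12, 42, 162, 642, 2562 for levels 1..5.
#'
#' @param level subdivision level, >= 1.
#' @return Integer vertex count.
#' @export
icosphere_count <- function(level) {
  stopifnot(level >= 1)
  as.integer(10 * 4^(level - 1) + 2)
}

# Canonical base icosahedron: fixed vertex order, outward-oriented faces.
base_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

# One midpoint-split subdivision with re-projection to the unit sphere.
# New vertices are appended in the lexicographic order of their (sorted)
# parent edge, so level-l vertices are a prefix of the level-(l+1) ordering.
subdivide_icosphere <- function(v, f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  eu <- unique(e)
  eu <- eu[order(eu[, 1], eu[, 2]), , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mid_idx <- stats::setNames(nrow(v) + seq_len(nrow(eu)), key(eu[, 1], eu[, 2]))
  mids <- (v[eu[, 1], , drop = FALSE] + v[eu[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  v2 <- rbind(v, mids)
  ab <- mid_idx[key(f[, 1], f[, 2])]
  bc <- mid_idx[key(f[, 2], f[, 3])]
  ca <- mid_idx[key(f[, 3], f[, 1])]
  f2 <- rbind(cbind(f[, 1], ab, ca), cbind(ab, f[, 2], bc),
              cbind(ca, bc, f[, 3]), cbind(ab, bc, ca))
  list(v = unname(v2), f = unname(f2))
}

#' Unit icosphere at a subdivision level
#'
#' Midpoint-split subdivision of the icosahedron with re-projection to the
#' unit sphere. Vertex ordering is deterministic and nested: the vertices of
#' level `l` are a prefix of the level `l + 1` ordering, which keeps
#' coarse-to-fine weight refinement index-stable.
#'
#' @param level subdivision level, >= 1 (level 1 is the base icosahedron with
#'   12 vertices; level 2 has 42).
#' @return A `triangle_mesh` on the unit sphere with
#'   [icosphere_count()]`(level)` vertices.
#' @export
icosphere <- function(level) {
  if (length(level) != 1L || level < 1) stop("level must be >= 1")
  key <- paste0("ico", level)
  cached <- get0(key, envir = .mtlseg_cache)
  if (!is.null(cached)) return(cached)
  m <- base_icosahedron()
  l <- 1
  while (l < level) {
    m <- subdivide_icosphere(m$v, m$f)
    l <- l + 1
  }
  out <- triangle_mesh(m$v, m$f)
  assign(key, out, envir = .mtlseg_cache)
  out
}

#' Validate that a mesh is a closed orientable genus-0 surface
#'
#' Checks the Euler characteristic (V - E + F = 2), that every edge is shared
#' by exactly two faces with opposite orientation, and that no face is
#' degenerate.
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_mesh <- function(mesh) {
  f <- mesh$faces
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate face (repeated vertex)")
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- paste(he[, 1], he[, 2])
  if (anyDuplicated(keys)) stop("inconsistent orientation: repeated half-edge")
  rev_keys <- paste(he[, 2], he[, 1])
  if (!all(rev_keys %in% keys)) stop("open mesh: boundary edge found")
  V <- nrow(mesh$vertices); Fc <- nrow(f); E <- nrow(he) / 2
  if (V - E + Fc != 2)
    stop("Euler characteristic ", V - E + Fc, " != 2 (not genus 0)")
  invisible(TRUE)
}

#' Concatenate per-structure meshes into one corresponded MTL surface
#'
#' The three structure surfaces are treated as one concatenated surface; the
#' concatenated vertex index is the structure offset plus the within-structure
#' index, and corresponds to the same anatomical location across all templates
#' of a library.
#'
#' @param meshes list of three `triangle_mesh` objects in HP, AM, EC order;
#'   their per-structure vertex counts define the library convention.
#' @param centers optional 3 x 3 matrix of radial parameterization centers
#'   (one row per structure, world mm).
#' @return A `corresponded_surface`.
#' @export
concat_surface <- function(meshes, centers = NULL) {
  if (length(meshes) != 3L) stop("expected three structure meshes (HP, AM, EC)")
  counts <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  structure(list(meshes = meshes, counts = counts, centers = centers),
            class = "corresponded_surface")
}

#' @rdname concat_surface
#' @param surface a `corresponded_surface`.
#' @export
split_surface <- function(surface) surface$meshes

#' @export
print.corresponded_surface <- function(x, ...) {
  cat(sprintf("<corresponded_surface> HP/AM/EC vertices: %s (total %d)\n",
              paste(x$counts, collapse = "/"), sum(x$counts)))
  invisible(x)
}

surface_vertices <- function(surface) {
  do.call(rbind, lapply(surface$meshes, function(m) m$vertices))
}

surface_vertex_structure <- function(surface) {
  rep(1:3, surface$counts)
}

surface_offsets <- function(surface) {
  c(0L, cumsum(surface$counts)[1:2])
}

# Rebuild a corresponded surface from a replacement concatenated vertex matrix.
surface_with_vertices <- function(surface, verts) {
  off <- surface_offsets(surface)
  meshes <- lapply(1:3, function(s) {
    m <- surface$meshes[[s]]
    m$vertices <- verts[off[s] + seq_len(surface$counts[s]), , drop = FALSE]
    m
  })
  concat_surface(meshes, surface$centers)
}

check_surfaces_compatible <- function(surfaces) {
  counts <- surfaces[[1]]$counts
  for (s in surfaces[-1])
    if (!identical(s$counts, counts))
      stop("per-structure vertex counts differ across surfaces")
  invisible(TRUE)
}

#' Write / read a triangle mesh as Wavefront OBJ
#'
#' Minimal `v`/`f` OBJ support; a `corresponded_surface` is stored as three
#' OBJ files plus a JSON sidecar recording structure ids, per-structure vertex
#' counts and parameterization centers.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output `.obj` path.
#' @return `path` (write) or a `triangle_mesh` (read).
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- matrix(as.numeric(unlist(strsplit(sub("^v ", "", vl), " +"))),
              ncol = 3, byrow = TRUE)
  fidx <- vapply(strsplit(sub("^f ", "", fl), " +"),
                 function(p) as.integer(sub("/.*", "", p)), integer(3))
  triangle_mesh(v, t(fidx))
}

#' @rdname write_obj
#' @param surface a `corresponded_surface`.
#' @param dir output directory for the 3-OBJ bundle + sidecar.
#' @export
write_surface_bundle <- function(surface, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- c("HP", "AM", "EC")
  for (s in 1:3)
    write_obj(surface$meshes[[s]], file.path(dir, paste0(ids[s], ".obj")))
  sidecar <- list(structures = ids, counts = surface$counts,
                  centers = surface$centers)
  jsonlite::write_json(sidecar, file.path(dir, "surface.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_obj
#' @export
read_surface_bundle <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "surface.json"),
                                 simplifyVector = TRUE)
  meshes <- lapply(seq_along(sidecar$structures), function(s) {
    m <- read_obj(file.path(dir, paste0(sidecar$structures[s], ".obj")))
    m$structure_id <- sidecar$structures[s]
    m
  })
  centers <- if (is.null(sidecar$centers)) NULL else as.matrix(sidecar$centers)
  concat_surface(meshes, centers)
}
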