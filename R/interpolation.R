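# Spherical interpolation of per-vertex quantities from a coarse icosphere
# level to arbitrary unit directions. Each target direction is located in its
# containing coarse spherical triangle; the value is the barycentric
# combination obtained by central (gnomonic) projection onto the triangle
# plane, which is a partition of unity and reproduces coarse-vertex values
# exactly.

# For each target direction, find the level-l face whose gnomonic barycentric
# coordinates are all non-negative (max-min over faces for robustness) and
# return the face's vertex indices + weights.
locate_on_icosphere <- function(directions, level) {
  ico <- icosphere(level)
  V <- ico$vertices
  Fq <- ico$faces
  n <- nrow(directions)
  vi <- matrix(0L, n, 3)
  w <- matrix(0, n, 3)
  # Face normals for a quick candidate ordering: target is in a face whose
  # centroid is close in direction.
  cent <- (V[Fq[, 1], ] + V[Fq[, 2], ] + V[Fq[, 3], ]) / 3
  cent <- cent / sqrt(rowSums(cent^2))
  sim <- directions %*% t(cent)
  ord <- apply(sim, 1, order, decreasing = TRUE)
  for (i in seq_len(n)) {
    d <- directions[i, ]
    best_minw <- -Inf
    for (f in ord[1:min(12, nrow(Fq)), i]) {
      tri <- Fq[f, ]
      A <- t(V[tri, ])  # 3x3, columns are corners
      bw <- tryCatch(solve(A, d), error = function(e) NULL)
      if (is.null(bw)) next
      s <- sum(bw)
      if (s <= 0) next
      bw <- bw / s
      mn <- min(bw)
      if (mn > best_minw) {
        best_minw <- mn
        vi[i, ] <- tri
        w[i, ] <- bw
      }
      if (mn >= -1e-12) break
    }
    if (best_minw < -1e-6)
      stop("failed to locate direction on icosphere (min weight ",
           signif(best_minw, 3), ")")
    # clamp tiny negatives and renormalize: partition of unity
    w[i, ] <- pmax(w[i, ], 0)
    w[i, ] <- w[i, ] / sum(w[i, ])
  }
  list(idx = vi, weights = w)
}

# Cached location of the full-resolution icosphere directions (level L) on a
# coarser level l: reused for every weight interpolation.
icosphere_transfer <- function(coarse_level, target_level) {
  key <- sprintf("xfer_%d_%d", coarse_level, target_level)
  cached <- get0(key, envir = .mtlseg_cache)
  if (!is.null(cached)) return(cached)
  loc <- locate_on_icosphere(icosphere(target_level)$vertices, coarse_level)
  assign(key, loc, envir = .mtlseg_cache)
  loc
}

#' Interpolate per-vertex values from a coarse icosphere level
#'
#' Values indexed by the vertices of the level-`level` icosphere are
#' interpolated to arbitrary unit directions by spherical (gnomonic
#' projection) barycentric interpolation within the containing coarse
#' triangle. Weights are non-negative and sum to one per target, so constant
#' fields are reproduced exactly and coarse vertices are interpolated to
#' their own value.
#'
#' @param coarse_values vector (length `m(level)`) or matrix
#'   (`m(level)` x k) of per-vertex values at the coarse level.
#' @param directions n x 3 matrix of unit directions (norm within 1e-6 of 1).
#' @param level coarse icosphere level.
#' @return Interpolated values: length-n vector or n x k matrix.
#' @export
interpolate_spherical <- function(coarse_values, directions, level) {
  directions <- matrix(directions, ncol = 3)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("directions must lie on the unit sphere (norm deviates > 1e-6)")
  directions <- directions / nrm
  m <- icosphere_count(level)
  vecin <- is.null(dim(coarse_values))
  cv <- if (vecin) matrix(coarse_values, ncol = 1) else as.matrix(coarse_values)
  if (nrow(cv) != m)
    stop("coarse_values must have ", m, " rows for level ", level)
  loc <- locate_on_icosphere(directions, level)
  out <- loc$weights[, 1] * cv[loc$idx[, 1], , drop = FALSE] +
    loc$weights[, 2] * cv[loc$idx[, 2], , drop = FALSE] +
    loc$weights[, 3] * cv[loc$idx[, 3], , drop = FALSE]
  if (vecin) as.vector(out) else out
}

# Nearest level-l sampling vertex (by direction) for each full-resolution
# icosphere vertex; nested ordering means sampling vertices are the first
# m(l) full-resolution vertices.
nearest_sampling_vertex <- function(coarse_level, target_level) {
  key <- sprintf("near_%d_%d", coarse_level, target_level)
  cached <- get0(key, envir = .mtlseg_cache)
  if (!is.null(cached)) return(cached)
  coarse <- icosphere(coarse_level)$vertices
  target <- icosphere(target_level)$vertices
  near <- max.col(target %*% t(coarse), ties.method = "first")
  assign(key, near, envir = .mtlseg_cache)
  near
}
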