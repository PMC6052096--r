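# Post-registration subset restriction, global weighted shape averaging and
# multi-level (coarse-to-fine icosahedron sampling) local weighted averaging.
#
# A single simplex weight vector per stage drives both the vertex-coordinate
# average and the feature mean/SD: the similarity being maximized is
#   O_subset = -(1/(V*9)) sum_v sum_f |Fbar_vf(w) - Fhat_vf(Sbar(w))| / sigma_vf(w)
# with Fbar/sigma the weighted mean/SD of the warped templates' true features
# and Fhat the features estimated on the test image along the weighted-mean
# surface. Weights are kept on the simplex by the squared-softmax
# reparameterization w_j = u_j^2 / sum(u^2); optimization is derivative-free
# Nelder-Mead from the uniform initialization, so the achieved objective
# never falls below its value at uniform weights.

#' Fusion configuration
#'
#' @param l0 coarsest icosahedron sampling level for local weighting
#'   (default 2: 42 sampling vertices per structure).
#' @param l_max finest sampling level (default 5; levels that cannot refine
#'   the correspondence sampling further are skipped).
#' @param tol level-advance tolerance on the `O_subset,l` gain.
#' @param nm_iters Nelder-Mead objective evaluations per weight optimization.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(l0 = 2, l_max = 5, tol = 1e-4, nm_iters = 200) {
  stopifnot(l0 >= 1, l0 <= l_max)
  structure(list(l0 = as.integer(l0), l_max = as.integer(l_max), tol = tol,
                 nm_iters = as.integer(nm_iters)), class = "fusion_config")
}

#' Vertex-wise weighted average of corresponded surfaces
#'
#' @param surfaces list of `corresponded_surface` objects sharing topology.
#' @param weights simplex vector (non-negative, sums to 1 within 1e-8), one
#'   weight per surface; or a `V_total x n` matrix of per-vertex simplex
#'   weights.
#' @return The averaged `corresponded_surface` (faces unchanged).
#' @export
average_surfaces <- function(surfaces, weights) {
  check_surfaces_compatible(surfaces)
  n <- length(surfaces)
  V <- sum(surfaces[[1]]$counts)
  if (is.matrix(weights)) {
    if (!identical(dim(weights), c(V, n)))
      stop("per-vertex weights must be V_total x n")
    if (max(abs(rowSums(weights) - 1)) > 1e-8)
      stop("per-vertex weights must sum to 1")
    out <- matrix(0, V, 3)
    for (j in seq_len(n))
      out <- out + weights[, j] * surface_vertices(surfaces[[j]])
  } else {
    if (length(weights) != n) stop("one weight per surface required")
    if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
    if (any(weights < 0)) stop("weights must be non-negative")
    out <- matrix(0, V, 3)
    for (j in seq_len(n))
      out <- out + weights[j] * surface_vertices(surfaces[[j]])
  }
  surface_with_vertices(surfaces[[1]], out)
}

#' Unweighted-average fusion baseline
#'
#' @param surfaces list of corresponded surfaces.
#' @return [average_surfaces()] with uniform weights.
#' @export
fuse_unweighted <- function(surfaces) {
  average_surfaces(surfaces, rep(1 / length(surfaces), length(surfaces)))
}

# Warp a template into test space and refresh all its components.
warp_template <- function(template, field, test) {
  wvol <- apply_to_volume(field, template$volume, geometry = test)
  wlab <- apply_to_volume(field, template$label, geometry = test)
  wsrf <- apply_to_surface(field, template$surface)
  make_template(template$id, wvol, wlab, wsrf)
}

#' Restrict a registered subset to the n_b most similar templates
#'
#' Recomputes the hybrid similarity on the warped templates (warped volumes,
#' surfaces and refreshed features) and keeps the top `n_b`, ties broken by
#' ascending id.
#'
#' @param warped_templates list of warped [make_template()] objects.
#' @param test the test `volume3d`.
#' @param stats the library's [library_feature_stats()].
#' @param cfg a [selection_config()] (`n_b` and similarity settings used).
#' @return A tibble `id, o_volume, o_surface, o_total, rank` of the retained
#'   templates.
#' @export
restrict_subset <- function(warped_templates, test, stats,
                            cfg = selection_config()) {
  if (cfg$n_b > length(warped_templates))
    stop("n_b exceeds the registered subset size")
  test_grad <- gradient_magnitude(test)
  scores <- t(vapply(warped_templates,
                     function(t) score_template(t, test, stats, cfg, test_grad),
                     numeric(3)))
  ids <- vapply(warped_templates, function(t) as.character(t$id), character(1))
  ord <- order(-scores[, "o_total"], ids)
  sel <- ord[seq_len(cfg$n_b)]
  tibble::tibble(id = ids[sel],
                 o_volume = scores[sel, "o_volume"],
                 o_surface = scores[sel, "o_surface"],
                 o_total = scores[sel, "o_total"],
                 rank = seq_len(cfg$n_b))
}

# Weighted per-vertex feature deviation objective. `W` is V x n_b (rows on
# the simplex), `feats` a list of n_b true feature matrices, `est` the
# estimated features along the weighted surface; the normalization SD is
# the weight-dependent subset SD unless a fixed `sdfix` is supplied.
subset_objective <- function(W, feats, est, sdfix = NULL) {
  V <- nrow(est)
  mu <- matrix(0, V, 9)
  for (j in seq_along(feats)) mu <- mu + W[, j] * feats[[j]]
  if (is.null(sdfix)) {
    var <- matrix(0, V, 9)
    for (j in seq_along(feats)) var <- var + W[, j] * (feats[[j]] - mu)^2
    sdfix <- sqrt(var)
  }
  -sum(abs(mu - est) / pmax(sdfix, 1e-6)) / length(est)
}

softmax_sq <- function(u) {
  s <- sum(u^2)
  if (s < 1e-12) rep(1 / length(u), length(u)) else u^2 / s
}

#' Optimize global fusion weights over the restricted subset
#'
#' Weights start uniform (1/n_b) and are optimized by Nelder-Mead on the
#' subset similarity; the simplex constraint is enforced by the
#' squared-softmax reparameterization. Deterministic.
#'
#' @param subset list of n_b >= 2 warped [make_template()] objects.
#' @param test the test `volume3d`.
#' @param cfg a [fusion_config()].
#' @return List with `weights` (simplex vector), `o_subset` (achieved
#'   objective), `surface` (the weighted-average surface) and
#'   `o_subset_uniform` (objective at the uniform initialization).
#' @export
optimize_global_weights <- function(subset, test, cfg = fusion_config()) {
  n <- length(subset)
  if (n < 2) stop("subset must contain at least 2 templates")
  surfaces <- lapply(subset, `[[`, "surface")
  feats <- lapply(subset, `[[`, "features")
  V <- nrow(feats[[1]])
  grad <- gradient_magnitude(test)
  obj_of <- function(w) {
    sbar <- average_surfaces(surfaces, w)
    est <- estimate_features_on_test(test, sbar, grad = grad)
    o <- subset_objective(matrix(w, V, n, byrow = TRUE), feats, est)
    if (!is.finite(o)) stop("non-finite fusion objective")
    o
  }
  fn <- function(u) -obj_of(softmax_sq(u))
  u0 <- rep(1, n)
  f0 <- fn(u0)
  opt <- stats::optim(u0, fn, method = "Nelder-Mead",
                      control = list(maxit = cfg$nm_iters, reltol = 1e-8))
  if (opt$value < f0 - 1e-9 * (1 + abs(f0))) { # flat objectives keep the init
    w <- softmax_sq(opt$par); o <- -opt$value
  } else {
    w <- softmax_sq(u0); o <- -f0
  }
  list(weights = w, o_subset = o,
       surface = average_surfaces(surfaces, w), o_subset_uniform = -f0)
}

level_of_count <- function(n) {
  l <- round(log((n - 2) / 10, 4)) + 1
  if (icosphere_count(l) != n)
    stop("vertex count ", n, " is not an icosphere subdivision count")
  as.integer(l)
}

# Full-objective evaluation for a per-vertex weight matrix.
eval_vertex_weights <- function(W, surfaces, feats, test, grad, sdfix = NULL) {
  sbar <- average_surfaces(surfaces, W)
  est <- estimate_features_on_test(test, sbar, grad = grad)
  list(surface = sbar, o = subset_objective(W, feats, est, sdfix))
}

#' Multi-level local weighted averaging
#'
#' Starting from the global weights replicated at every level-`l0` sampling
#' vertex, each level optimizes the n_b-simplex weight vector at every
#' sampling vertex by Nelder-Mead on the locally restricted objective (the
#' full-resolution vertices whose nearest sampling vertex it is), then
#' interpolates the weights to all vertices by spherical barycentric
#' interpolation, renormalizes per vertex, rebuilds the locally weighted
#' surface and advances to the next level only while the subset similarity
#' keeps improving.
#'
#' @param subset list of n_b warped templates (as passed to
#'   [optimize_global_weights()]).
#' @param test the test `volume3d`.
#' @param global_weights simplex vector from [optimize_global_weights()].
#' @param cfg a [fusion_config()].
#' @return List with `surface` (final locally weighted surface),
#'   `vertex_weights` (V_total x n_b), `o_subset`, `level_reached` and the
#'   per-level objective `trace`.
#' @export
optimize_local_weights <- function(subset, test, global_weights,
                                   cfg = fusion_config()) {
  n <- length(subset)
  surfaces <- lapply(subset, `[[`, "surface")
  feats <- lapply(subset, `[[`, "features")
  counts <- surfaces[[1]]$counts
  if (length(unique(counts)) != 1)
    stop("per-structure vertex counts must match across structures")
  L <- level_of_count(counts[1])
  V <- sum(counts)
  grad <- gradient_magnitude(test)
  spacing <- grid_spacing(test)

  Xs <- array(0, c(V, 3, n))
  Ft <- array(0, c(V, 9, n))
  for (j in seq_len(n)) {
    Xs[, , j] <- surface_vertices(surfaces[[j]])
    Ft[, , j] <- feats[[j]]
  }
  faces_list <- lapply(surfaces[[1]]$meshes, function(m) m$faces - 1L)
  voffset <- as.integer(surface_offsets(surfaces[[1]]))
  vstruct <- as.integer(surface_vertex_structure(surfaces[[1]]))

  W <- matrix(global_weights, V, n, byrow = TRUE)
  best <- eval_vertex_weights(W, surfaces, feats, test, grad)
  best_W <- W
  trace <- c(global = best$o)
  level_reached <- NA_integer_

  for (l in seq(cfg$l0, cfg$l_max)) {
    m <- icosphere_count(l)
    if (m >= counts[1] && l > level_of_count(counts[1])) break # saturated
    m_eff <- min(m, counts[1])
    near <- nearest_sampling_vertex(min(l, L), L)
    part <- integer(V)
    for (s in 1:3)
      part[voffset[s] + seq_len(counts[s])] <- (s - 1L) * m_eff + near
    # sampling-vertex init: current per-vertex weights at the sampling
    # vertices themselves (nested prefix ordering)
    w0 <- matrix(0, 3 * m_eff, n)
    for (s in 1:3)
      w0[(s - 1) * m_eff + seq_len(m_eff), ] <-
        best_W[voffset[s] + seq_len(m_eff), , drop = FALSE]
    res <- cpp_local_sweep(as.vector(test$data), as.vector(grad$data),
                           dim(test$data), spacing, grid_origin(test),
                           Xs, Ft, w0, part - 1L, vstruct, faces_list,
                           voffset, cached_offsets(spacing), feature_radii,
                           cfg$nm_iters, 0)
    wl <- res$weights
    # interpolate sampling-vertex weights to all vertices, per structure
    if (m_eff < counts[1]) {
      loc <- icosphere_transfer(min(l, L), L)
      Wnew <- matrix(0, V, n)
      for (s in 1:3) {
        ws <- wl[(s - 1) * m_eff + seq_len(m_eff), , drop = FALSE]
        Wnew[voffset[s] + seq_len(counts[s]), ] <-
          loc$weights[, 1] * ws[loc$idx[, 1], , drop = FALSE] +
          loc$weights[, 2] * ws[loc$idx[, 2], , drop = FALSE] +
          loc$weights[, 3] * ws[loc$idx[, 3], , drop = FALSE]
      }
    } else {
      Wnew <- matrix(0, V, n)
      for (s in 1:3)
        Wnew[voffset[s] + seq_len(counts[s]), ] <-
          wl[(s - 1) * m_eff + seq_len(m_eff), , drop = FALSE]
    }
    if (min(Wnew) < -1e-9) stop("negative interpolated weight: ", min(Wnew))
    Wnew[Wnew < 0] <- 0
    Wnew <- Wnew / rowSums(Wnew)
    cand <- eval_vertex_weights(Wnew, surfaces, feats, test, grad)
    gain <- cand$o - best$o
    trace <- c(trace, stats::setNames(cand$o, paste0("l", l)))
    if (cand$o > best$o) {
      best <- cand
      best_W <- Wnew
      level_reached <- l
    }
    if (gain < cfg$tol) break
    if (m_eff >= counts[1]) break # finer levels cannot refine further
  }

  list(surface = best$surface, vertex_weights = best_W, o_subset = best$o,
       level_reached = level_reached, trace = trace)
}

# Geometric validity of an averaged structure mesh: closed manifold,
# positive enclosed volume, non-empty voxelization.
check_structure_mesh <- function(mesh, geometry, structure_id) {
  tryCatch(check_mesh(mesh), error = function(e)
    stop("structure ", structure_id, ": ", conditionMessage(e), call. = FALSE))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], ]; b <- v[f[, 2], ]; c <- v[f[, 3], ]
  vol6 <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
              a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
              a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1]))
  if (vol6 <= 0)
    stop("structure ", structure_id,
         ": non-positive enclosed volume (degenerate or inverted mesh)")
  invisible(TRUE)
}

#' Convert the final fused surface into the output segmentation
#'
#' @param surface the final `corresponded_surface`.
#' @param geometry the test `volume3d` defining the output grid.
#' @return A `label_volume` on the test grid.
#' @export
finalize_segmentation <- function(surface, geometry) {
  ids <- c("HP", "AM", "EC")
  for (s in 1:3)
    check_structure_mesh(surface$meshes[[s]], geometry, ids[s])
  out <- surface_to_label(surface, geometry)
  for (s in 1:3)
    if (!any(out$data == s))
      stop("structure ", ids[s], " is empty after averaging")
  out
}
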