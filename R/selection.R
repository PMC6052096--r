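# Hybrid surface + volume template similarity and subset selection.
#
# O_total = O_volume + w_surface * O_surface, where O_volume is a masked
# volume similarity (cross-correlation or NMI) and O_surface is the
# (negative) normalized deviation between the template's true vertex
# features and those estimated on the test image along the template surface.
# O_surface is divided by (V_total * 9) so w_surface is independent of the
# correspondence sampling resolution.

#' Selection configuration
#'
#' @param w_surface weight of the surface similarity term in the hybrid
#'   score. O_surface here is normalized per vertex-feature, so the weight is
#'   on the scale of the volume correlation; default 1.
#' @param n_a initial template-subset size (default 17).
#' @param n_b final template-subset size (default 8).
#' @param volume_similarity `"cc"` (Pearson cross-correlation) or `"nmi"`
#'   (normalized mutual information).
#' @return A `selection_config` list.
#' @export
selection_config <- function(w_surface = 1.0, n_a = 17, n_b = 8,
                             volume_similarity = c("cc", "nmi")) {
  volume_similarity <- match.arg(volume_similarity)
  stopifnot(w_surface >= 0, n_b >= 1, n_b <= n_a)
  structure(list(w_surface = w_surface, n_a = as.integer(n_a),
                 n_b = as.integer(n_b),
                 volume_similarity = volume_similarity),
            class = "selection_config")
}

#' Surface-based similarity between true and estimated features
#'
#' `O_surface = -(1 / (V * 9)) * sum_v sum_f |F_vf - Fhat_vf| / sigma_vf`
#' with the library SD floored at 1e-6. Zero iff the feature matrices are
#' identical; always non-positive.
#'
#' @param true_features,est_features V x 9 feature matrices.
#' @param stats [library_feature_stats()] of the template library.
#' @return A non-positive scalar score.
#' @export
o_surface <- function(true_features, est_features, stats) {
  if (!identical(dim(true_features), dim(est_features)) ||
      !identical(dim(true_features), dim(stats$sd)))
    stop("feature/statistics shape mismatch")
  sd <- pmax(stats$sd, 1e-6)
  -sum(abs(true_features - est_features) / sd) / length(true_features)
}

#' Volume-based similarity within a mask
#'
#' Cross-correlation is the Pearson correlation of the masked intensities
#' (in `[-1, 1]`); NMI is `(H(A) + H(B)) / H(A, B)` from a 32 x 32 joint
#' histogram over the masked voxels (in `[1, 2]`).
#'
#' @param template_vol,test_vol `volume3d` objects on the same grid.
#' @param mask a `binary_mask` with >= 100 foreground voxels.
#' @param method `"cc"` or `"nmi"`.
#' @param bins histogram bins per axis for NMI.
#' @return Similarity score.
#' @export
o_volume <- function(template_vol, test_vol, mask, method = c("cc", "nmi"),
                     bins = 32) {
  method <- match.arg(method)
  if (!same_geometry(template_vol, test_vol) ||
      !same_geometry(template_vol, mask))
    stop("volumes and mask must share geometry")
  a <- template_vol$data[mask$data]
  b <- test_vol$data[mask$data]
  if (length(a) < 100) stop("mask must contain at least 100 voxels")
  if (method == "cc") {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
      stop("constant masked intensities: cross-correlation undefined")
    stats::cor(a, b)
  } else {
    nmi_score(a, b, bins)
  }
}

nmi_score <- function(a, b, bins = 32) {
  cut_idx <- function(x) {
    r <- range(x)
    if (diff(r) < 1e-12) return(rep(1L, length(x)))
    pmin(pmax(floor((x - r[1]) / diff(r) * bins) + 1L, 1L), bins)
  }
  ia <- cut_idx(a); ib <- cut_idx(b)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pa <- rowSums(matrix(p, bins)); pb <- colSums(matrix(p, bins))
  hj <- ent(p)
  if (hj < 1e-12) return(2)  # both constant: perfectly redundant
  (ent(pa) + ent(pb)) / hj
}

#' Hybrid similarity
#'
#' @param o_vol volume similarity score.
#' @param o_surf surface similarity score (non-positive).
#' @param w_surface weighting constant.
#' @return `o_vol + w_surface * o_surf`.
#' @export
o_total <- function(o_vol, o_surf, w_surface) o_vol + w_surface * o_surf

#' Template: image + label + corresponded surface + true features
#'
#' @param id template identifier (character or integer; ties in ranking are
#'   broken by ascending id).
#' @param volume a `volume3d` (intensity-normalized working scale).
#' @param label the template's `label_volume`.
#' @param surface the template's `corresponded_surface`.
#' @param features optional precomputed true feature matrix (computed with
#'   boundary = voxelized surface if omitted).
#' @return A `template` object.
#' @export
make_template <- function(id, volume, label, surface, features = NULL) {
  if (!same_geometry(volume, label)) stop("volume/label geometry mismatch")
  if (is.null(features))
    features <- compute_vertex_features(volume, surface)
  structure(list(id = id, volume = volume, label = label, surface = surface,
                 features = features), class = "template")
}

#' Template library
#'
#' Aggregates N >= 2 templates sharing surface topology, their feature
#' statistics, and the registration mask (geometric union of all template
#' labels dilated 5 times).
#'
#' @param templates list of [make_template()] objects.
#' @return A `template_library`.
#' @export
template_library <- function(templates) {
  if (length(templates) < 2) stop("template library needs N >= 2 templates")
  check_surfaces_compatible(lapply(templates, `[[`, "surface"))
  stats <- library_feature_stats(lapply(templates, `[[`, "features"))
  union_fg <- Reduce(`|`, lapply(templates, function(t) t$label$data != 0))
  geom <- templates[[1]]$label
  mask <- dilate_label(binary_mask(union_fg, geom$affine), 5)
  structure(list(templates = templates, stats = stats,
                 registration_mask = mask),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> N = %d templates, %d surface vertices\n",
              length(x$templates), nrow(x$stats$mean)))
  invisible(x)
}

library_ids <- function(library) {
  vapply(library$templates, function(t) as.character(t$id), character(1))
}

# Score one template against the test image (native, unwarped placement:
# library and test share the common space).
score_template <- function(template, test, stats, cfg, test_grad) {
  mask <- dilate_label(template$label, 3)
  ov <- o_volume(template$volume, test, mask, method = cfg$volume_similarity)
  est <- estimate_features_on_test(test, template$surface, grad = test_grad)
  os <- o_surface(template$features, est, stats)
  c(o_volume = ov, o_surface = os,
    o_total = o_total(ov, os, cfg$w_surface))
}

#' Rank a template library against a test image and select a subset
#'
#' Computes the hybrid similarity for every template (surface term from
#' estimated features along each template's surface mapped on the test
#' image) and returns the top `n` templates, sorted by `O_total` descending
#' with ties broken by ascending template id. Deterministic.
#'
#' @param library a `template_library`.
#' @param test a `volume3d` in the library's common space.
#' @param n subset size (1 <= n <= N).
#' @param cfg a [selection_config()].
#' @param exclude_id optional template id to exclude (for test subjects that
#'   are themselves library members).
#' @return A tibble with columns `id`, `o_volume`, `o_surface`, `o_total`,
#'   `rank` for the selected templates.
#' @export
select_subset <- function(library, test, n, cfg = selection_config(),
                          exclude_id = NULL) {
  templates <- library$templates
  if (!is.null(exclude_id))
    templates <- Filter(function(t) !as.character(t$id) %in%
                          as.character(exclude_id), templates)
  if (length(templates) == 0) stop("empty library")
  if (n < 1 || n > length(templates))
    stop("n must be between 1 and ", length(templates))
  test_grad <- gradient_magnitude(test)
  scores <- t(vapply(templates,
                     function(t) score_template(t, test, library$stats, cfg,
                                                test_grad),
                     numeric(3)))
  ids <- vapply(templates, function(t) as.character(t$id), character(1))
  ord <- order(-scores[, "o_total"], ids)
  sel <- ord[seq_len(n)]
  tibble::tibble(id = ids[sel],
                 o_volume = scores[sel, "o_volume"],
                 o_surface = scores[sel, "o_surface"],
                 o_total = scores[sel, "o_total"],
                 rank = seq_len(n))
}
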