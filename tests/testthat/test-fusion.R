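make_sphere_surface <- function(radius, center = c(16, 16, 16), level = 3) {
  ico <- icosphere(level)
  m <- icosphere_count(level)
  mk <- function(r, ctr) triangle_mesh(ico$vertices * r +
                                         matrix(ctr, m, 3, byrow = TRUE),
                                       ico$faces)
  concat_surface(list(mk(radius, center),
                      mk(radius * 0.5, center + c(10, 0, 0)),
                      mk(radius * 0.5, center - c(10, 0, 0))))
}

test_that("average_surfaces is a vertex-wise convex combination", {
  s4 <- make_sphere_surface(4)
  s8 <- make_sphere_surface(8)
  avg <- average_surfaces(list(s4, s8), c(0.5, 0.5))
  r <- sqrt(rowSums(sweep(avg$meshes[[1]]$vertices, 2, c(16, 16, 16))^2))
  expect_lt(max(abs(r - 6)), 1e-10)
  # identical inputs are a fixed point for any simplex weights
  same <- average_surfaces(list(s4, s4, s4), c(0.2, 0.3, 0.5))
  expect_lt(max(abs(surface_vertices(same) - surface_vertices(s4))), 1e-12)
  # random weights vs per-vertex loop
  set.seed(41)
  w <- runif(3); w <- w / sum(w)
  surfs <- list(s4, s8, make_sphere_surface(6))
  got <- surface_vertices(average_surfaces(surfs, w))
  want <- w[1] * surface_vertices(surfs[[1]]) +
    w[2] * surface_vertices(surfs[[2]]) + w[3] * surface_vertices(surfs[[3]])
  expect_lt(max(abs(got - want)), 1e-12)
  expect_error(average_surfaces(list(s4, s8), c(0.7, 0.2)), "sum to 1")
  # averaged surfaces stay inside the convex hull of the inputs
  lo <- pmin(apply(surface_vertices(s4), 2, min), apply(surface_vertices(s8), 2, min))
  hi <- pmax(apply(surface_vertices(s4), 2, max), apply(surface_vertices(s8), 2, max))
  expect_true(all(t(surface_vertices(avg)) >= lo - 1e-9 &
                  t(surface_vertices(avg)) <= hi + 1e-9))
})

test_that("fuse_unweighted equals uniform-weight averaging", {
  s4 <- make_sphere_surface(4); s8 <- make_sphere_surface(8)
  expect_equal(surface_vertices(fuse_unweighted(list(s4, s8))),
               surface_vertices(average_surfaces(list(s4, s8), c(0.5, 0.5))))
})

test_that("restrict_subset equals an independent recomputation", {
  co <- fx_small_cohort()
  lib <- co$library
  test <- co$tests[[1]]$volume
  cfg <- selection_config(n_a = 6, n_b = 3)
  # native templates stand in for warped ones: the operation contract is
  # score-and-rank whatever templates it is given
  res <- restrict_subset(lib$templates, test, lib$stats, cfg)
  expect_equal(nrow(res), 3)
  grad <- mtlseg:::gradient_magnitude(test)
  manual <- vapply(lib$templates, function(t) {
    ov <- o_volume(t$volume, test, dilate_label(t$label, 3), "cc")
    est <- estimate_features_on_test(test, t$surface, grad = grad)
    o_total(ov, o_surface(t$features, est, lib$stats), cfg$w_surface)
  }, numeric(1))
  ids <- vapply(lib$templates, function(t) as.character(t$id), character(1))
  want <- ids[order(-manual, ids)][1:3]
  expect_equal(res$id, want)
  # identity restriction
  cfg_all <- selection_config(n_a = 6, n_b = 6)
  expect_equal(nrow(restrict_subset(lib$templates, test, lib$stats, cfg_all)),
               6)
  expect_error(restrict_subset(lib$templates[1:2], test, lib$stats, cfg),
               "exceeds")
})

test_that("global weight optimization favors the matching template", {
  co <- fx_small_cohort()
  lib <- co$library
  tpl1 <- lib$templates[[1]]
  # subset of 3; the test image IS template 1's volume
  subset <- lib$templates[1:3]
  res <- optimize_global_weights(subset, tpl1$volume, fusion_config())
  expect_gt(res$weights[1], 0.6)
  expect_equal(sum(res$weights), 1, tolerance = 1e-12)
  expect_true(all(res$weights >= 0))
  expect_gte(res$o_subset, res$o_subset_uniform)
})

test_that("identical templates leave global weights at the uniform init", {
  tpl <- fx_template(7)
  subset <- list(tpl, tpl, tpl)
  res <- optimize_global_weights(subset, tpl$volume, fusion_config())
  expect_equal(res$weights, rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("constant per-vertex weights reproduce the global average surface", {
  co <- fx_small_cohort()
  surfs <- lapply(co$library$templates[1:3], `[[`, "surface")
  w <- c(0.5, 0.3, 0.2)
  V <- sum(surfs[[1]]$counts)
  got <- average_surfaces(surfs, matrix(w, V, 3, byrow = TRUE))
  want <- average_surfaces(surfs, w)
  expect_lt(max(abs(surface_vertices(got) - surface_vertices(want))), 1e-12)
})

test_that("local weighting recovers a left/right chimera test image", {
  co <- fx_small_cohort()
  a <- co$library$templates[[1]]
  b <- co$library$templates[[2]]
  # chimera: template a's intensities for x < 32, template b's for x >= 32
  chim <- a$volume$data
  chim[33:64, , ] <- b$volume$data[33:64, , ]
  chim_vol <- volume3d(chim, a$volume$affine)
  res <- optimize_local_weights(list(a, b), chim_vol, c(0.5, 0.5),
                                fusion_config())
  W <- res$vertex_weights
  x <- surface_vertices(a$surface)[, 1]
  expect_gt(mean(W[x < 30, 1]), 0.5)
  expect_lt(mean(W[x > 34, 1]), 0.5)
  # weights stay on the simplex
  expect_lt(max(abs(rowSums(W) - 1)), 1e-9)
  expect_gte(min(W), 0)
  # local refinement never falls below its initialization
  expect_gte(res$o_subset, res$trace[["global"]])
})

test_that("finalize_segmentation validates meshes and produces test-grid labels", {
  ph <- fx_phantom(7)
  lab <- finalize_segmentation(ph$surface, ph$volume)
  expect_gte(min(dice(ph$label, lab)), 0.95)
  expect_identical(dim(lab$data), dim(ph$volume$data))
  # inverted orientation is rejected with the structure named
  bad <- ph$surface
  bad$meshes[[2]]$faces <- bad$meshes[[2]]$faces[, c(1, 3, 2)]
  expect_error(finalize_segmentation(bad, ph$volume), "AM")
})
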