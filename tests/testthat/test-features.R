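make_two_phase_ball <- function(inner = 50, outer = 150, radius = 6) {
  d <- c(32L, 32L, 32L)
  g <- as.matrix(expand.grid(x = 0:31, y = 0:31, z = 0:31))
  r <- sqrt(colSums((t(g) - 15.5)^2))
  vol <- array(ifelse(r < radius, inner, outer), d)
  list(vol = volume3d(vol), label = fx_ball_label(radius))
}

test_that("feature layout is NI/RI/IG over 3, 5, 7 mm", {
  ph <- fx_phantom(7)
  f <- compute_vertex_features(ph$volume, ph$surface)
  expect_equal(ncol(f), 9)
  expect_equal(nrow(f), sum(ph$surface$counts))
  expect_equal(colnames(f),
               c("NI_3mm", "NI_5mm", "NI_7mm", "RI_3mm", "RI_5mm", "RI_7mm",
                 "IG_3mm", "IG_5mm", "IG_7mm"))
  expect_true(all(is.finite(f)))
})

test_that("RI and IG take their analytic values on a two-phase ball", {
  tp <- make_two_phase_ball(50, 150)
  srf <- label_to_surface(tp$label, "HP", level = 3)
  ico <- icosphere(3)
  far <- function(ctr) triangle_mesh(ico$vertices * 0.45 +
                                       matrix(ctr, 162, 3, byrow = TRUE),
                                     ico$faces)
  surf <- concat_surface(list(srf$mesh, far(c(3, 3, 3)), far(c(28, 3, 3))))
  f <- compute_vertex_features(tp$vol, surf, boundary = tp$label)
  hp <- seq_len(162)
  # RI = 2(150 - 50)/(150 + 50) = 1 exactly (means of constant phases)
  expect_lt(max(abs(f[hp, "RI_5mm"] - 1)), 1e-10)
  # constant-phase image: gradient is non-zero only at the boundary shell
  const <- volume3d(array(42, c(32, 32, 32)))
  fc <- compute_vertex_features(const, surf, boundary = tp$label)
  expect_true(all(fc[hp, c("IG_3mm", "IG_5mm", "IG_7mm")] == 0))
})

test_that("features equal the triple-loop oracle on a random phantom", {
  set.seed(11)
  d <- c(24L, 24L, 24L)
  vol <- array(rnorm(prod(d), 100, 15), d)
  g <- as.matrix(expand.grid(x = 0:23, y = 0:23, z = 0:23))
  inside <- sqrt(colSums((t(g) - 11.5)^2)) < 6
  lab <- label_volume(array(as.integer(inside), d))
  srf <- label_to_surface(lab, "HP", level = 2)
  ico <- icosphere(2)
  far <- function(ctr) triangle_mesh(ico$vertices * 0.4 +
                                       matrix(ctr, 42, 3, byrow = TRUE),
                                     ico$faces)
  surf <- concat_surface(list(srf$mesh, far(c(2, 2, 2)), far(c(21, 2, 2))))
  f <- compute_vertex_features(volume3d(vol), surf, boundary = lab)
  set.seed(12)
  pick <- sample(42, 20)
  want <- oracle_features(vol, lab$data, srf$mesh$vertices[pick, , drop = FALSE],
                          rep(1L, 20))
  expect_lt(max(abs(f[pick, ] - want)), 1e-10)
})

test_that("features are invariant to integer-voxel translation", {
  set.seed(13)
  d <- c(28L, 28L, 28L)
  vol <- array(rnorm(prod(d), 100, 10), d)
  g <- as.matrix(expand.grid(x = 0:27, y = 0:27, z = 0:27))
  inside <- array(sqrt(colSums((t(g) - 11.5)^2)) < 5, d)
  sh <- c(3L, 2L, 1L)
  vol2 <- array(0, d); ins2 <- array(FALSE, d)
  vol2[(1 + sh[1]):28, (1 + sh[2]):28, (1 + sh[3]):28] <-
    vol[1:(28 - sh[1]), 1:(28 - sh[2]), 1:(28 - sh[3])]
  ins2[(1 + sh[1]):28, (1 + sh[2]):28, (1 + sh[3]):28] <-
    inside[1:(28 - sh[1]), 1:(28 - sh[2]), 1:(28 - sh[3])]
  mk <- function(v, ins) {
    lab <- label_volume(array(as.integer(ins), d))
    srf <- label_to_surface(lab, "HP", level = 2)
    ico <- icosphere(2)
    far <- function(ctr) triangle_mesh(ico$vertices * 0.4 +
                                         matrix(ctr, 42, 3, byrow = TRUE),
                                       ico$faces)
    surf <- concat_surface(list(srf$mesh, far(c(2, 2, 2)), far(c(25, 2, 2))))
    compute_vertex_features(volume3d(v), surf, boundary = lab)[1:42, ]
  }
  f1 <- mk(vol, inside)
  f2 <- mk(vol2, ins2)
  # interior vertices see identical neighborhoods (boundary spheres touch
  # the shifted-in zeros, so compare only the common support)
  ok <- rowSums(abs(f1 - f2)) < 1e-6
  expect_gt(mean(ok), 0.8)
  expect_lt(max(abs(f1[ok, ] - f2[ok, ])), 1e-6)
})

test_that("RI is antisymmetric under swapping inner/outer intensities", {
  a <- make_two_phase_ball(50, 150)
  b <- make_two_phase_ball(150, 50)
  srf <- label_to_surface(a$label, "HP", level = 2)
  ico <- icosphere(2)
  far <- function(ctr) triangle_mesh(ico$vertices * 0.4 +
                                       matrix(ctr, 42, 3, byrow = TRUE),
                                     ico$faces)
  surf <- concat_surface(list(srf$mesh, far(c(3, 3, 3)), far(c(28, 3, 3))))
  fa <- compute_vertex_features(a$vol, surf, boundary = a$label)
  fb <- compute_vertex_features(b$vol, surf, boundary = b$label)
  hp <- 1:42
  expect_lt(max(abs(fa[hp, 4:6] + fb[hp, 4:6])), 1e-10)
  expect_true(all(abs(fa[hp, 4:6]) <= 2))
})

test_that("estimated features reproduce true features in the identity configuration", {
  tpl <- fx_template(7)
  est <- estimate_features_on_test(tpl$volume, tpl$surface)
  expect_lt(max(abs(est - tpl$features)), 1e-10)
  expect_identical(attr(est, "provenance"), "estimated")
})

test_that("library feature statistics use the population SD", {
  f1 <- matrix(1, 5, 9); f3 <- matrix(3, 5, 9)
  st <- library_feature_stats(list(f1, f3))
  expect_true(all(st$mean == 2))
  expect_true(all(st$sd == 1))
  st0 <- library_feature_stats(list(f1, f1, f1))
  expect_true(all(st0$sd == 0))
  set.seed(14)
  fs <- lapply(1:4, function(i) matrix(rnorm(45), 5, 9))
  st <- library_feature_stats(fs)
  cell_mean <- mean(sapply(fs, function(f) f[3, 5]))
  cell_sd <- sqrt(mean((sapply(fs, function(f) f[3, 5]) - cell_mean)^2))
  expect_equal(st$mean[3, 5], cell_mean, tolerance = 1e-12)
  expect_equal(st$sd[3, 5], cell_sd, tolerance = 1e-12)
  expect_error(library_feature_stats(list(f1)), "at least 2")
})
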