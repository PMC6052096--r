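test_that("registration similarity terms match textbook oracles", {
  set.seed(31)
  d <- c(12L, 12L, 12L)
  a <- volume3d(array(rnorm(prod(d), 100, 10), d))
  b <- volume3d(array(rnorm(prod(d), 100, 10), d))
  mask <- binary_mask(array(TRUE, d))
  expect_equal(o_vol_reg(a, a, mask), 1.0)
  shifted <- volume3d(a$data + 17)
  expect_equal(o_vol_reg(shifted, a, mask), 1.0, tolerance = 1e-12)
  expect_equal(o_vol_reg(a, b, mask),
               oracle_cor(a$data[mask$data], b$data[mask$data]),
               tolerance = 1e-10)

  ft <- rnorm(100); fs <- rnorm(100)
  expect_equal(o_surf_reg(ft, ft), 1.0)
  expect_equal(o_surf_reg(ft, -ft), -1.0)
  expect_equal(o_surf_reg(ft, fs), oracle_cor(ft, fs), tolerance = 1e-12)
  expect_error(o_surf_reg(ft, rep(1, 100)), "variance")
})

test_that("smoothness penalty vanishes for affine fields and matches the loop oracle", {
  z <- deformation_field(array(0, c(4, 5, 6, 3)), c(0, 0, 0), 8)
  expect_equal(smoothness_penalty(z), 0)
  const <- deformation_field(array(2, c(4, 5, 6, 3)), c(0, 0, 0), 8)
  expect_equal(smoothness_penalty(const), 0)
  set.seed(32)
  lat <- array(rnorm(4 * 5 * 6 * 3), c(4, 5, 6, 3))
  f <- deformation_field(lat, c(0, 0, 0), 8)
  expect_equal(smoothness_penalty(f), oracle_smoothness(lat),
               tolerance = 1e-12)
})

test_that("field application honors the backward-map contract", {
  ph <- fx_phantom(7)
  vol <- ph$volume
  zero <- deformation_field(array(0, c(10, 10, 10, 3)), c(-8, -8, -8), 8)
  expect_identical(apply_to_volume(zero, vol)$data, vol$data)
  s0 <- apply_to_surface(zero, ph$surface)
  expect_identical(surface_vertices(s0), surface_vertices(ph$surface))

  # constant field d = (2,0,0): surface forward map moves by exactly -d
  cf <- deformation_field(array(rep(c(2, 0, 0), each = 1000),
                                c(10, 10, 10, 3)), c(-8, -8, -8), 8)
  sc <- apply_to_surface(cf, ph$surface)
  delta <- surface_vertices(sc) - surface_vertices(ph$surface)
  expect_lt(max(abs(sweep(delta, 2, c(-2, 0, 0)))), 1e-9)

  # smooth random capped field: forward-backward composition residual
  set.seed(33)
  lat <- array(rnorm(3000, 0, 0.8), c(10, 10, 10, 3))
  lat[abs(lat) > 2.4] <- 2.4
  f <- deformation_field(lat, c(-8, -8, -8), 8)
  sf <- apply_to_surface(f, ph$surface)
  x <- surface_vertices(sf)
  y_back <- x + field_displacement(f, x)
  expect_lt(max(sqrt(rowSums((y_back - surface_vertices(ph$surface))^2))),
            0.05)
})

test_that("registering an image to itself leaves the field at zero", {
  tpl <- fx_template(7)
  mask <- dilate_label(tpl$label, 5)
  f <- register_hybrid(tpl, tpl$volume, mask, registration_config(sweeps = 2))
  expect_lt(max(abs(f$lattice)), 0.2)
  # monotone objective within each level
  for (tr in attr(f, "trace")) expect_true(all(diff(tr) >= -1e-9))
})

test_that("a 2 mm translation is recovered within 0.5 mm inside the mask", {
  tpl <- fx_template(7)
  ph <- fx_phantom(7)
  sh <- ph$volume$data * 0
  sh[3:64, , ] <- ph$volume$data[1:62, , ]
  sh[1:2, , ] <- 30
  test <- normalize_intensity(volume3d(sh, ph$volume$affine), ph$brain_mask,
                              100, 10)
  mask <- dilate_label(tpl$label, 5)
  f <- register_hybrid(tpl, test, mask, registration_config())
  idx <- which(mask$data, arr.ind = TRUE) - 1L
  d <- field_displacement(f, idx)  # 1 mm identity affine: voxel == mm
  err <- sqrt(rowSums(sweep(d, 2, c(-2, 0, 0))^2))
  expect_lt(mean(err), 0.5)
  # displacement cap keeps the field locally invertible (positive Jacobian)
  expect_lt(max(sqrt(rowSums(d^2))), f$cap + 1e-9)
})

test_that("cross-subject registration improves label overlap", {
  tpl <- fx_template(7)
  ph2 <- fx_phantom(8)
  test <- normalize_intensity(ph2$volume, ph2$brain_mask, 100, 10)
  mask <- dilate_label(binary_mask(tpl$label$data != 0 | ph2$label$data != 0,
                                   tpl$label$affine), 5)
  f <- register_hybrid(tpl, test, mask, registration_config())
  pre <- mean(dice(ph2$label, tpl$label))
  post <- mean(dice(ph2$label, apply_to_volume(f, tpl$label, geometry = test)))
  expect_gt(post, pre)
  expect_gt(post, 0.85)
  # final objective consistent with the R-level similarity functions
  w <- apply_to_volume(f, tpl$volume, geometry = test)
  obj <- attr(f, "objective")
  expect_gt(obj, o_vol_reg(w, test, mask) - 0.2)  # surface term adds the rest
})

test_that("deformation fields round-trip through NIfTI + JSON", {
  set.seed(34)
  lat <- array(rnorm(4 * 5 * 6 * 3, 0, 1), c(4, 5, 6, 3))
  f <- deformation_field(lat, c(-8, -4, 0), 8, cap = 3.2)
  base <- tempfile()
  write_deformation_field(f, base)
  back <- read_deformation_field(base)
  expect_lt(max(abs(back$lattice - lat)), 1e-12)
  expect_equal(back$origin, f$origin)
  expect_equal(back$spacing, f$spacing)
  expect_equal(back$cap, f$cap)
})
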