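test_that("icosphere vertex counts follow the subdivision sequence", {
  expect_equal(vapply(1:5, icosphere_count, integer(1)),
               c(12L, 42L, 162L, 642L, 2562L))
  for (l in 1:4) {
    m <- icosphere(l)
    expect_equal(nrow(m$vertices), icosphere_count(l))
    expect_silent(check_mesh(m))  # closed, orientable, Euler char 2
    expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 1e-12)
  }
  expect_error(icosphere(0))
})

test_that("icosphere levels are nested with prefix vertex ordering", {
  for (l in 1:3) {
    coarse <- icosphere(l)$vertices
    fine <- icosphere(l + 1)$vertices
    expect_equal(fine[seq_len(nrow(coarse)), ], coarse)
  }
})

test_that("label_to_surface recovers analytic radii of ball and ellipsoid", {
  ball <- fx_ball_label(radius = 6)
  srf <- label_to_surface(ball, "HP", level = 3)
  radii <- sqrt(rowSums(sweep(srf$mesh$vertices, 2, srf$center)^2))
  expect_true(all(abs(radii - 6) < 0.5))
  expect_silent(check_mesh(srf$mesh))

  g <- as.matrix(expand.grid(x = 0:31, y = 0:31, z = 0:31))
  off <- sweep(g, 2, c(15.5, 15.5, 15.5))
  inside <- (off[, 1] / 8)^2 + (off[, 2] / 5)^2 + (off[, 3] / 4)^2 < 1
  ell <- label_volume(array(as.integer(inside), c(32, 32, 32)))
  se <- label_to_surface(ell, "HP", level = 3)
  # vertex closest to the +x axis sits near the 8 mm semi-axis
  dirs <- se$directions
  vx <- which.max(dirs[, 1])
  r <- sqrt(sum((se$mesh$vertices[vx, ] - se$center)^2))
  expect_lt(abs(r - 8), 0.5)
})

test_that("label_to_surface rejects disconnected structures", {
  d <- array(0L, c(16, 16, 16))
  d[3:5, 3:5, 3:5] <- 1L
  d[11:13, 11:13, 11:13] <- 1L
  expect_error(label_to_surface(label_volume(d), "HP", level = 2),
               "6-connected")
})

test_that("surface_to_label matches analytic volume and round-trips", {
  # sphere mesh of radius 5 mm rasterized on a 1 mm grid
  ico <- icosphere(4)
  mesh <- triangle_mesh(ico$vertices * 5 +
                          matrix(c(12.25, 12.25, 12.25), 642, 3, byrow = TRUE),
                        ico$faces, "HP")
  geom <- volume3d(array(0, c(25, 25, 25)))
  empty <- triangle_mesh(ico$vertices * 0.45 +
                           matrix(c(3, 3, 3), 642, 3, byrow = TRUE),
                         ico$faces)
  surf <- concat_surface(list(mesh, empty_off <- triangle_mesh(
    ico$vertices * 0.45 + matrix(c(20, 3, 3), 642, 3, byrow = TRUE),
    ico$faces), triangle_mesh(
    ico$vertices * 0.45 + matrix(c(3, 20, 3), 642, 3, byrow = TRUE),
    ico$faces)))
  lab <- surface_to_label(surf, geom)
  expect_lt(abs(sum(lab$data == 1) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.05)

  # label -> surface -> label round trip on a synthetic ball
  ball <- fx_ball_label(radius = 6)
  srf <- label_to_surface(ball, "HP", level = 4)
  rt <- surface_to_label(concat_surface(list(
    srf$mesh,
    triangle_mesh(ico$vertices * 0.45 + matrix(c(2, 2, 2), 642, 3, byrow = TRUE), ico$faces),
    triangle_mesh(ico$vertices * 0.45 + matrix(c(28, 2, 2), 642, 3, byrow = TRUE), ico$faces))),
    volume3d(array(0, c(32, 32, 32))))
  expect_gte(oracle_dice(ball$data, rt$data, 1L), 0.95)
})

test_that("concat and split are inverse with fixed vertex offsets", {
  ico3 <- icosphere(3); ico4 <- icosphere(4)
  mk <- function(ico, id) triangle_mesh(ico$vertices, ico$faces, id)
  s <- concat_surface(list(mk(ico4, "HP"), mk(ico4, "AM"), mk(ico4, "EC")))
  expect_equal(sum(s$counts), 3 * 642)
  back <- split_surface(s)
  expect_equal(back[[2]]$vertices, ico4$vertices)
  # a mixed-resolution bundle is rejected by downstream consumers
  s2 <- concat_surface(list(mk(ico3, "HP"), mk(ico4, "AM"), mk(ico4, "EC")))
  expect_error(average_surfaces(list(s, s2), c(0.5, 0.5)))
})

test_that("OBJ bundle round-trips a corresponded surface", {
  ph <- fx_phantom(7)
  dir <- tempfile()
  write_surface_bundle(ph$surface, dir)
  back <- read_surface_bundle(dir)
  expect_equal(back$counts, ph$surface$counts)
  for (s in 1:3) {
    expect_lt(max(abs(back$meshes[[s]]$vertices -
                        ph$surface$meshes[[s]]$vertices)), 1e-6)
    expect_identical(back$meshes[[s]]$faces, ph$surface$meshes[[s]]$faces)
  }
})

test_that("spherical interpolation is exact at vertices and matches the oracle", {
  set.seed(4)
  lvl <- 2
  vals <- rnorm(icosphere_count(lvl))
  # constant field reproduced everywhere (partition of unity)
  dirs <- matrix(rnorm(600), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  const <- interpolate_spherical(rep(3.5, icosphere_count(lvl)), dirs, lvl)
  expect_lt(max(abs(const - 3.5)), 1e-10)
  # coarse-vertex identity
  vcoarse <- icosphere(lvl)$vertices
  atv <- interpolate_spherical(vals, vcoarse, lvl)
  expect_lt(max(abs(atv - vals)), 1e-10)
  # random targets vs gnomonic oracle
  got <- interpolate_spherical(vals, dirs, lvl)
  want <- oracle_spherical_interp(vals, dirs, lvl)
  expect_lt(max(abs(got - want)), 1e-8)
  expect_error(interpolate_spherical(vals, matrix(c(1, 1, 1), 1), lvl),
               "unit sphere")
})
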