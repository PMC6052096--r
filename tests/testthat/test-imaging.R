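test_that("NIfTI round-trip preserves affine and data", {
  set.seed(1)
  aff <- diag(c(1.5, 1.2, 2, 1))
  aff[1:3, 4] <- c(-10, 5, 3)
  vol <- volume3d(array(rnorm(16^3), c(16, 16, 16)), aff)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, type = "intensity")
  expect_lt(max(abs(back$affine - aff)), 1e-4)
  expect_lt(max(abs(back$data - vol$data)) / max(abs(vol$data)), 1e-6)

  lab <- label_volume(array(sample(0:3, 16^3, replace = TRUE), c(16, 16, 16)),
                      aff)
  fl <- tempfile(fileext = ".nii.gz")
  write_volume(lab, fl)
  labback <- read_volume(fl)
  expect_s3_class(labback, "label_volume")
  expect_identical(labback$data, lab$data)
})

test_that("invalid volumes are rejected", {
  expect_error(label_volume(array(7L, c(8, 8, 8))), "codebook")
  expect_error(volume3d(array(1, c(8, 8))), "non-3D")
  expect_error(volume3d(array(NA_real_, c(8, 8, 8))), "finite")
  expect_error(volume3d(array(1, c(8, 8, 8)), matrix(0, 4, 4)),
               "non-invertible")
})

test_that("6-connected dilation matches L1-ball counts and is monotone", {
  d <- array(0L, c(16, 16, 16))
  d[8, 8, 8] <- 1L
  m <- binary_mask(d != 0)
  expect_equal(sum(dilate_label(m, 1)$data), 7)
  # brute-force L1-ball count oracle for 3 iterations
  g <- expand.grid(x = -4:4, y = -4:4, z = -4:4)
  expect_equal(sum(dilate_label(m, 3)$data),
               sum(abs(g$x) + abs(g$y) + abs(g$z) <= 3))
  # monotone growth
  prev <- m$data
  for (k in 1:4) {
    cur <- dilate_label(m, k)$data
    expect_true(all(cur[prev]))
    prev <- cur
  }
  # full-grid fixed point
  full <- binary_mask(array(TRUE, c(8, 8, 8)))
  expect_equal(sum(dilate_label(full, 2)$data), 8^3)
  expect_error(dilate_label(binary_mask(array(FALSE, c(8, 8, 8))), 1),
               "empty")
})

test_that("intensity normalization is an affine z-score within the mask", {
  set.seed(2)
  raw <- array(rnorm(12^3, 100, 10), c(12, 12, 12))
  vol <- volume3d(raw)
  mask <- binary_mask(array(TRUE, c(12, 12, 12)))
  nz <- normalize_intensity(vol, mask)
  expect_equal(mean(nz$data), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(nz$data)), 1, tolerance = 1e-12)
  # a voxel one SD above the mask mean maps to 1
  vol$data[1] <- mean(vol$data[-1]) # neutralize, then recompute stats
  mu <- mean(vol$data); s <- sd(as.vector(vol$data))
  expect_equal(normalize_intensity(vol, mask)$data[1], (vol$data[1] - mu) / s,
               tolerance = 1e-12)
  ramped <- volume3d(array(seq(90, 110, length.out = 12^3), c(12, 12, 12)))
  nr <- normalize_intensity(ramped, mask)
  mu <- mean(ramped$data); s <- sd(as.vector(ramped$data))
  expect_equal(nr$data[3, 4, 5], (ramped$data[3, 4, 5] - mu) / s,
               tolerance = 1e-12)
  # idempotence
  nz2 <- normalize_intensity(nz, mask)
  expect_lt(max(abs(nz2$data - nz$data)), 1e-12)
  expect_error(normalize_intensity(volume3d(array(5, c(12, 12, 12))), mask),
               "variance")
})

test_that("trilinear sampling matches the 8-corner oracle", {
  set.seed(3)
  vol <- volume3d(array(rnorm(10 * 11 * 12), c(10, 11, 12)))
  # voxel-center identity
  expect_equal(trilinear_sample(vol, c(3, 4, 5)), vol$data[4, 5, 6])
  # midpoint linearity on a locally linear profile
  ramp <- volume3d(array(rep(2 * (0:9), 11 * 12), c(10, 11, 12)))
  expect_equal(trilinear_sample(ramp, c(2.5, 5, 5)), 5)
  # random points vs oracle
  pts <- cbind(runif(100, 0, 9), runif(100, 0, 10), runif(100, 0, 11))
  got <- trilinear_sample(vol, pts)
  want <- apply(pts, 1, function(p) oracle_trilinear1(vol$data, p))
  expect_lt(max(abs(got - want)), 1e-10)
  # out-of-grid fill
  expect_equal(trilinear_sample(vol, c(-5, 0, 0), fill = -1), -1)
})
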