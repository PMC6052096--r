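test_that("dice matches its set-based definition", {
  d <- c(12L, 12L, 12L)
  a <- array(0L, d); a[2:6, 2:6, 2:5] <- 1L          # 100 voxels
  b <- array(0L, d); b[2:6, 2:6, 3:6] <- 1L          # 100 voxels, 75 overlap
  la <- label_volume(a); lb <- label_volume(b)
  expect_equal(dice(la, la, "HP"), 1.0)
  expect_equal(dice(la, lb, "HP"), 2 * 75 / 200)
  expect_equal(dice(la, lb, "HP"), dice(lb, la, "HP"))
  # both-empty convention
  expect_equal(dice(la, lb, "AM"), 1.0)
  set.seed(51)
  r1 <- label_volume(array(sample(0:3, prod(d), TRUE), d))
  r2 <- label_volume(array(sample(0:3, prod(d), TRUE), d))
  for (s in 1:3)
    expect_equal(dice(r1, r2, s), oracle_dice(r1$data, r2$data, s),
                 tolerance = 1e-12)
  expect_error(dice(la, label_volume(a, diag(c(2, 2, 2, 1)))), "differ")
})

test_that("cohens_d uses the pooled-SD definition", {
  expect_equal(cohens_d(c(10, 12), c(6, 8)), 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(5, 7, 9), c(5, 7, 9)), 0)
  set.seed(52)
  x <- rnorm(20, 100, 9); y <- rnorm(15, 90, 11)
  sp <- sqrt((19 * var(x) + 14 * var(y)) / 33)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_error(cohens_d(c(1), c(2, 3)), "n >= 2")
})

test_that("atrophy flags use a strict z < -2 rule", {
  r <- atrophy_flag(2500, 3000, 200)
  expect_equal(r$z, -2.5)
  expect_true(r$flag)
  expect_false(atrophy_flag(3000, 3000, 200)$flag)
  # boundary: exactly -2 is not flagged
  expect_false(atrophy_flag(2600, 3000, 200)$flag)
  expect_error(atrophy_flag(2500, 3000, 0), "positive")
})
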