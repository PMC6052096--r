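test_that("o_surface is a normalized non-positive deviation", {
  set.seed(21)
  V <- 30
  tf <- matrix(rnorm(V * 9), V, 9)
  st <- list(mean = tf, sd = matrix(abs(rnorm(V * 9, 1, 0.2)), V, 9))
  expect_identical(o_surface(tf, tf, st), 0)
  # one cell deviating by exactly one library SD
  ef <- tf
  ef[4, 2] <- tf[4, 2] + st$sd[4, 2]
  expect_equal(o_surface(tf, ef, st), -1 / (V * 9), tolerance = 1e-12)
  # random deviation vs scalar-loop oracle
  ef <- tf + matrix(rnorm(V * 9, 0, 0.5), V, 9)
  expect_equal(o_surface(tf, ef, st), oracle_o_surface(tf, ef, st$sd),
               tolerance = 1e-12)
  expect_lte(o_surface(tf, ef, st), 0)
  expect_error(o_surface(tf, ef[1:10, ], st), "mismatch")
})

test_that("o_volume cross-correlation and NMI match independent oracles", {
  set.seed(22)
  d <- c(12L, 12L, 12L)
  a <- volume3d(array(rnorm(prod(d), 100, 10), d))
  mask <- binary_mask(array(TRUE, d))
  expect_equal(o_volume(a, a, mask, "cc"), 1.0)
  neg <- volume3d(array(2 * mean(a$data) - a$data, d))  # mirrored intensities
  expect_equal(o_volume(a, neg, mask, "cc"), -1.0, tolerance = 1e-12)
  b <- volume3d(array(rnorm(prod(d), 100, 10), d))
  expect_equal(o_volume(a, b, mask, "cc"),
               oracle_cor(a$data[mask$data], b$data[mask$data]),
               tolerance = 1e-8)
  expect_equal(o_volume(a, b, mask, "nmi"),
               oracle_nmi(a$data[mask$data], b$data[mask$data]),
               tolerance = 1e-8)
  expect_error(o_volume(volume3d(array(1, d)), b, mask, "cc"), "constant")
})

test_that("o_total combines the terms linearly", {
  expect_equal(o_total(0.8, -0.5, 2), -0.2)
  expect_equal(o_total(0.8, -0.5, 0), 0.8)
  expect_equal(o_total(1, 0, 3.1), 1)
})

test_that("self-match ranks first with O_total = 1 and ranking is stable", {
  co <- fx_small_cohort()
  lib <- co$library
  tpl1 <- lib$templates[[1]]
  cfg <- selection_config(n_a = 6, n_b = 3)
  sel <- select_subset(lib, tpl1$volume, n = 6, cfg)
  expect_equal(sel$id[1], as.character(tpl1$id))
  expect_equal(sel$o_total[1], 1.0, tolerance = 1e-9)
  expect_equal(sel$o_surface[1], 0, tolerance = 1e-12)
  # n = N returns all templates sorted by score
  expect_equal(nrow(sel), 6)
  expect_true(all(diff(sel$o_total) <= 1e-12))
  # permutation invariance
  lib2 <- template_library(rev(lib$templates))
  sel2 <- select_subset(lib2, tpl1$volume, n = 6, cfg)
  expect_equal(sel2$id, sel$id)
  expect_equal(sel2$o_total, sel$o_total, tolerance = 1e-10)
})

test_that("w_surface limits recover pure-volume and pure-surface rankings", {
  co <- fx_small_cohort()
  lib <- co$library
  test <- co$tests[[1]]$volume
  sel_v <- select_subset(lib, test, 6, selection_config(w_surface = 0))
  # w = 0: ranking equals the volume-only ordering
  expect_equal(sel_v$o_total, sel_v$o_volume, tolerance = 1e-12)
  expect_equal(order(-sel_v$o_volume, sel_v$id), seq_len(6))
  sel_s <- select_subset(lib, test, 6, selection_config(w_surface = 1e6))
  expect_equal(sel_s$id[order(-sel_s$o_surface, sel_s$id)], sel_s$id)
})
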