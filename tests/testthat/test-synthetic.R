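test_that("phantom generation is bit-reproducible for a fixed seed", {
  a <- make_phantom(phantom_spec(), seed = 99)
  b <- make_phantom(phantom_spec(), seed = 99)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$label$data, b$label$data)
  expect_equal(surface_vertices(a$surface), surface_vertices(b$surface))
})

test_that("structures are adjacent, non-overlapping, star-shaped and labelled", {
  ph <- fx_phantom(7)
  counts <- table(ph$label$data)
  expect_true(all(c("1", "2", "3") %in% names(counts)))
  # star-shape validation passed during generation within the attempt budget
  expect_lte(ph$meta$attempt, 10)
  # surfaces exist with the library topology
  expect_equal(ph$surface$counts, rep(642L, 3))
  for (m in ph$surface$meshes) expect_silent(check_mesh(m))
})

test_that("atrophy hits the target volumetric fraction within 3%", {
  base <- make_phantom(phantom_spec(), seed = 42)
  atro <- make_phantom(phantom_spec(atrophy = c(HP = 0.7)), seed = 42)
  ratio <- label_volumes(atro$label)[["HP"]] / label_volumes(base$label)[["HP"]]
  expect_lt(abs(ratio / 0.7 - 1), 0.03)
  # untouched structures unchanged in distribution (same seed, same draw)
  expect_identical(base$meta$coefs, atro$meta$coefs)
})

test_that("noise-free phantoms take exactly the specified region means", {
  ph <- make_phantom(phantom_spec(noise_sd = 0), seed = 5)
  ints <- phantom_spec()$intensities
  expect_true(all(ph$volume$data[ph$label$data == 1] == ints[["HP"]]))
  expect_true(all(ph$volume$data[ph$label$data == 3] == ints[["EC"]]))
  outside <- ph$label$data == 0 & ph$brain_mask$data
  expect_true(all(ph$volume$data[outside] == ints[["tissue"]]))
})

test_that("cohorts are seed-stable with group structure and detectable atrophy", {
  spec <- cohort_spec(n_templates = 4, n_test_controls = 1,
                      n_test_patients = 1, seed = 77)
  c1 <- make_cohort(spec)
  c2 <- make_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$tests[[1]]$volume$data, c2$tests[[1]]$volume$data)
  expect_error(make_cohort(cohort_spec(n_templates = 1, seed = 1)),
               "N >= 2")
  # ground-truth control vs patient HP volumes at the spec's example size
  vc <- sapply(1:15, function(i)
    label_volumes(make_phantom(phantom_spec(), seed = 5000 + i)$label)[["HP"]])
  vp <- sapply(1:15, function(i)
    label_volumes(make_phantom(phantom_spec(atrophy = c(HP = 0.70, EC = 0.85)),
                               seed = 6000 + i)$label)[["HP"]])
  expect_gt(cohens_d(vc, vp), 1)
})
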