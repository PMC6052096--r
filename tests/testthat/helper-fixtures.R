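# Shared fixtures, built once per test run and memoized.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_env)) assign(name, expr, envir = .fx_env)
  get(name, envir = .fx_env)
}

fx_phantom <- function(seed = 7, ...) {
  fx(paste0("ph", seed), make_phantom(phantom_spec(...), seed = seed))
}

# Normalized-template view of a phantom.
fx_template <- function(seed = 7) {
  fx(paste0("tpl", seed), {
    ph <- fx_phantom(seed)
    nv <- normalize_intensity(ph$volume, ph$brain_mask, 100, 10)
    make_template(paste0("t", seed), nv, ph$label, ph$surface)
  })
}

# Small library of 6 templates + 1 control test subject (unit tests).
fx_small_cohort <- function() {
  fx("small_cohort",
     make_cohort(cohort_spec(n_templates = 6, n_test_controls = 1,
                             seed = 515)))
}

# A ball-only label volume on a 32^3 grid (analytic geometry tests).
fx_ball_label <- function(radius = 6, center = c(15.5, 15.5, 15.5)) {
  key <- paste0("ball", radius, paste(center, collapse = "_"))
  fx(key, {
    d <- c(32L, 32L, 32L)
    g <- as.matrix(expand.grid(x = 0:31, y = 0:31, z = 0:31))
    inside <- sqrt(colSums((t(g) - center)^2)) < radius
    label_volume(array(as.integer(inside), d))
  })
}
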