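# Scaled-down template-library-size experiment: segmentation accuracy as a
# function of the library fraction, with control/patient proportions
# preserved in every random sub-library.

utils::globalVariables(c("stage", "structure"))

#' Template-library-size experiment
#'
#' For each fraction of the template library, random sub-libraries are drawn
#' (seeded; control/patient proportions preserved) and every test subject is
#' re-segmented against them. Fraction 1 uses the full library once (it is
#' the degenerate case: the same seed path reproduces the baseline result
#' exactly).
#'
#' @param cohort a [make_cohort()] result with test subjects.
#' @param fractions library fractions to test (default `c(1, 1/2, 1/3, 1/4,
#'   1/5)`).
#' @param repeats random sub-library draws per fraction (default 5; ignored
#'   for fraction 1).
#' @param cfg a [segment_config()]; `n_a`/`n_b` are capped at the
#'   sub-library size.
#' @param seed seed for the sub-library draws.
#' @param test_idx optional subset of test-subject indices to use.
#' @return A tibble with one row per (fraction, repeat, test, structure):
#'   columns `fraction`, `n_library`, `rep`, `test_id`, `structure`, `dice`.
#' @export
library_size_experiment <- function(cohort, fractions = c(1, 1/2, 1/3, 1/4, 1/5),
                                    repeats = 5, cfg = segment_config(),
                                    seed = 1, test_idx = NULL) {
  stopifnot(repeats >= 1)
  templates <- cohort$library$templates
  groups <- vapply(templates, function(t) attr(t, "group") %||% "control",
                   character(1))
  N <- length(templates)
  tests <- cohort$tests
  if (!is.null(test_idx)) tests <- tests[test_idx]

  run_once <- function(library, rep_i, fraction) {
    cfg2 <- cfg
    n <- length(library$templates)
    cfg2$selection$n_a <- min(cfg$selection$n_a, n)
    cfg2$selection$n_b <- min(cfg$selection$n_b, cfg2$selection$n_a)
    out <- NULL
    for (s in tests) {
      r <- segment_mtl(s$volume, library, cfg2, truth = s$label)
      d <- dice(s$label, r$label)
      out <- rbind(out, tibble::tibble(
        fraction = fraction, n_library = n, rep = rep_i, test_id = s$id,
        structure = names(d), dice = unname(d)))
    }
    out
  }

  results <- NULL
  for (fr in fractions) {
    if (abs(fr - 1) < 1e-12) {
      results <- rbind(results, run_once(cohort$library, 1L, 1))
      next
    }
    n_sub <- round(N * fr)
    if (n_sub < 2) stop("fraction ", fr, " yields fewer than 2 templates")
    for (rp in seq_len(repeats)) {
      set.seed((seed * 1000L + round(1000 * fr) + rp) %% .Machine$integer.max)
      pick <- proportional_sample(groups, n_sub)
      sub <- template_library(templates[pick])
      results <- rbind(results, run_once(sub, rp, fr))
    }
  }
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample n indices preserving group proportions as closely as possible.
proportional_sample <- function(groups, n) {
  tab <- table(groups)
  quota <- round(tab / sum(tab) * n)
  # fix rounding so the quotas sum to n
  while (sum(quota) > n) quota[which.max(quota)] <- quota[which.max(quota)] - 1
  while (sum(quota) < n) quota[which.min(quota)] <- quota[which.min(quota)] + 1
  picks <- integer(0)
  for (g in names(quota)) {
    idx <- which(groups == g)
    k <- min(quota[[g]], length(idx))
    picks <- c(picks, sample(idx, k))
  }
  sort(picks)
}

#' Summarize a library-size experiment by fraction and structure
#'
#' @param results a [library_size_experiment()] tibble.
#' @return A tibble `fraction, structure, mean_dice`.
#' @export
summarize_library_size <- function(results) {
  agg <- stats::aggregate(dice ~ fraction + structure, data = results, FUN = mean)
  names(agg)[names(agg) == "dice"] <- "mean_dice"
  tibble::as_tibble(agg[order(-agg$fraction, agg$structure), ])
}

utils::globalVariables(c("dice", "fraction"))
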