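# End-to-end segmentation pipeline: hybrid template selection, boundary-
# weighted registration, subset restriction, global and local weighted
# averaging, label synthesis.

#' Bundle of stage configurations for [segment_mtl()]
#'
#' @param selection a [selection_config()].
#' @param registration a [registration_config()].
#' @param fusion a [fusion_config()].
#' @return A `segment_config` list.
#' @export
segment_config <- function(selection = selection_config(),
                           registration = registration_config(),
                           fusion = fusion_config()) {
  structure(list(selection = selection, registration = registration,
                 fusion = fusion), class = "segment_config")
}

# Stage accuracy: template-set stages (initial subset, registration,
# restriction) carry the mean per-template Dice of the current set — a set
# of candidate templates has no single consensus segmentation yet — while
# the weighting stages carry the Dice of the fused surface.
stage_row <- function(stage, similarity, d) {
  if (is.null(d)) d <- c(HP = NA_real_, AM = NA_real_, EC = NA_real_)
  tibble::tibble(stage = stage, similarity = similarity,
                 dice_hp = d[["HP"]], dice_am = d[["AM"]], dice_ec = d[["EC"]],
                 mean_dice = mean(d))
}

set_dice <- function(truth, templates) {
  if (is.null(truth)) return(NULL)
  rowMeans(vapply(templates, function(t) dice(truth, t$label), numeric(3)))
}

fused_dice <- function(truth, label) {
  if (is.null(truth)) return(NULL)
  dice(truth, label)
}

#' Segment the mesiotemporal structures of a test image
#'
#' Runs the full pipeline: initial `n_a` subset selection with the hybrid
#' surface/volume similarity, boundary-weighted non-linear registration of
#' each retained template, restriction to the `n_b` most similar warped
#' templates, global weighted shape averaging, multi-level local weighted
#' averaging and label synthesis. Deterministic for fixed inputs and
#' configuration.
#'
#' @param test the test `volume3d` (intensity-normalized working scale, in
#'   the library's common space).
#' @param library a [template_library()].
#' @param cfg a [segment_config()].
#' @param truth optional ground-truth `label_volume`; when given, the stage
#'   report carries per-stage Dice values.
#' @param exclude_id optional library id to exclude (self-segmentation
#'   guard for test subjects that are library members).
#' @return List with `label` (final `label_volume`), `surface` (final fused
#'   surface), `stage_report` (tibble in pipeline order), `selection` and
#'   `restriction` tibbles, `global` and `local` fusion results.
#' @export
segment_mtl <- function(test, library, cfg = segment_config(), truth = NULL,
                        exclude_id = NULL) {
  n_avail <- length(library$templates) - length(exclude_id)
  if (cfg$selection$n_a > n_avail)
    stop("n_a (", cfg$selection$n_a, ") exceeds the library size (",
         n_avail, ")")
  withstage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
  }

  report <- NULL
  sel <- withstage("selection",
    select_subset(library, test, cfg$selection$n_a, cfg$selection,
                  exclude_id = exclude_id))
  by_id <- stats::setNames(library$templates, library_ids(library))
  subset_a <- by_id[sel$id]
  report <- rbind(report, stage_row("initial_subset", mean(sel$o_total),
                                    set_dice(truth, subset_a)))

  warped <- withstage("registration", lapply(subset_a, function(t) {
    field <- register_hybrid(t, test, library$registration_mask,
                             cfg$registration)
    warp_template(t, field, test)
  }))
  warped_dice <- if (is.null(truth)) NULL else
    tibble::tibble(id = sel$id,
                   dice = unname(vapply(warped, function(t)
                     mean(dice(truth, t$label)), numeric(1))))
  report <- rbind(report, stage_row("registration", NA_real_,
                                    set_dice(truth, warped)))

  res <- withstage("restriction",
    restrict_subset(warped, test, library$stats, cfg$selection))
  subset_b <- stats::setNames(warped, sel$id)[res$id]
  report <- rbind(report, stage_row("restricted_subset", mean(res$o_total),
                                    set_dice(truth, subset_b)))
  # unweighted-average fusion of the restricted subset: the label-fusion
  # baseline the weighted stages are compared against
  unweighted_dice <- if (is.null(truth)) NULL else
    dice(truth, surface_to_label(
      fuse_unweighted(lapply(subset_b, `[[`, "surface")), test))

  glob <- withstage("global_weighting",
    optimize_global_weights(subset_b, test, cfg$fusion))
  lab3 <- surface_to_label(glob$surface, test)
  report <- rbind(report, stage_row("global_weighting", glob$o_subset,
                                    fused_dice(truth, lab3)))

  loc <- withstage("local_weighting",
    optimize_local_weights(subset_b, test, glob$weights, cfg$fusion))
  final_label <- withstage("finalize",
    finalize_segmentation(loc$surface, test))
  report <- rbind(report, stage_row("local_weighting", loc$o_subset,
                                    fused_dice(truth, final_label)))

  list(label = final_label, surface = loc$surface, stage_report = report,
       selection = sel, restriction = res, global = glob, local = loc,
       warped_dice = warped_dice, unweighted_dice = unweighted_dice)
}

#' Plot the per-stage Dice trajectory of a segmentation
#'
#' @param result a [segment_mtl()] result with truth-based stage report.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_stage_report <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  rep <- result$stage_report
  long <- tibble::tibble(
    stage = factor(rep(rep$stage, 3), levels = rep$stage),
    structure = rep(c("HP", "AM", "EC"), each = nrow(rep)),
    dice = c(rep$dice_hp, rep$dice_am, rep$dice_ec))
  ggplot2::ggplot(long, ggplot2::aes(x = stage, y = dice,
                                     group = structure,
                                     colour = structure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pipeline stage", y = "Dice index") +
    ggplot2::theme_minimal()
}
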