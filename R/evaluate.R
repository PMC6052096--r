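# Evaluation metrics: Dice overlap, Cohen's d effect size, z-score atrophy
# flags.

#' Dice similarity index between two label volumes
#'
#' `D = 2 |M intersect A| / (|M| + |A|)`. When both labels are empty for a
#' structure the Dice is defined as 1 (perfect agreement on absence).
#'
#' @param m,a `label_volume` objects on the same grid (manual and automated).
#' @param structure structure name/code, or `NULL` for all three.
#' @return Dice in `[0, 1]`; a named vector over HP/AM/EC when
#'   `structure = NULL`.
#' @export
dice <- function(m, a, structure = NULL) {
  if (!same_geometry(m, a)) stop("label geometries differ")
  one <- function(code) {
    mm <- m$data == code
    aa <- a$data == code
    nm <- sum(mm); na <- sum(aa)
    if (nm + na == 0) return(1)
    2 * sum(mm & aa) / (nm + na)
  }
  if (is.null(structure))
    vapply(stats::setNames(1:3, c("HP", "AM", "EC")), one, numeric(1))
  else one(as_structure_code(structure))
}

#' Cohen's d for control-vs-patient volumes
#'
#' `(mean_controls - mean_patients) / pooled SD`; positive when patients are
#' smaller than controls (atrophy).
#'
#' @param control_volumes,patient_volumes numeric vectors (mm^3), each of
#'   length >= 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(control_volumes, patient_volumes) {
  nc <- length(control_volumes); np <- length(patient_volumes)
  if (nc < 2 || np < 2) stop("each group needs n >= 2")
  sp <- sqrt(((nc - 1) * stats::var(control_volumes) +
              (np - 1) * stats::var(patient_volumes)) / (nc + np - 2))
  if (sp < 1e-12) stop("zero pooled SD")
  (mean(control_volumes) - mean(patient_volumes)) / sp
}

#' Volume z-score and atrophy flag
#'
#' `z = (volume - control_mean) / control_sd`; flagged when `z < -2`
#' (strictly below).
#'
#' @param volume structure volume (mm^3).
#' @param control_mean,control_sd normative statistics (`control_sd > 0`).
#' @return List with `z` and logical `flag`.
#' @export
atrophy_flag <- function(volume, control_mean, control_sd) {
  if (control_sd <= 0) stop("control_sd must be positive")
  z <- (volume - control_mean) / control_sd
  list(z = z, flag = z < -2)
}
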