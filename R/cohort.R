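# Synthetic cohorts: template libraries plus labelled test subjects with
# known ground truth, all driven by one master seed.

#' Cohort specification
#'
#' @param n_templates number of library templates (>= 2).
#' @param n_test_controls,n_test_patients test subjects per group.
#' @param template_patient_frac fraction of library templates drawn with the
#'   patient (atrophied) shape distribution (default 0.6).
#' @param atrophy named volumetric atrophy fractions for the patient group
#'   (default `c(HP = 0.70, EC = 0.85)`).
#' @param seed master seed; fixes the entire cohort bit-exactly.
#' @param spec base [phantom_spec()] shared by all subjects.
#' @param surface_level correspondence sampling level.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_templates, n_test_controls = 0, n_test_patients = 0,
                        template_patient_frac = 0.6,
                        atrophy = c(HP = 0.70, EC = 0.85), seed = 1,
                        spec = phantom_spec(), surface_level = 4) {
  stopifnot(n_templates >= 0, n_test_controls >= 0, n_test_patients >= 0)
  structure(list(n_templates = n_templates,
                 n_test_controls = n_test_controls,
                 n_test_patients = n_test_patients,
                 template_patient_frac = template_patient_frac,
                 atrophy = atrophy, seed = seed, spec = spec,
                 surface_level = surface_level),
            class = "cohort_spec")
}

# Pipeline working intensity scale (positive, so ratio-based contrast
# features stay well-defined); see the methods vignette.
working_scale <- c(mean = 100, sd = 10)

normalize_subject <- function(phantom) {
  normalize_intensity(phantom$volume, phantom$brain_mask,
                      target_mean = working_scale["mean"],
                      target_sd = working_scale["sd"])
}

#' Generate a synthetic cohort
#'
#' Draws library templates and test subjects from the same shape-variability
#' distribution; patient subjects (and the patient fraction of the library)
#' get atrophied structures. Every subject's seed is derived from the master
#' seed, and the manifest records all of them, so the cohort is bit-exactly
#' reproducible.
#'
#' @param cspec a [cohort_spec()].
#' @return List with `library` (a [template_library()]), `tests` (list of
#'   subjects: normalized `volume`, ground-truth `label`, `group`, `id`) and
#'   `manifest` (tibble of ids, roles, groups and seeds).
#' @export
make_cohort <- function(cspec) {
  set.seed(cspec$seed)
  n_tpat <- round(cspec$n_templates * cspec$template_patient_frac)
  total <- cspec$n_templates + cspec$n_test_controls + cspec$n_test_patients
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  roles <- c(rep("template", cspec$n_templates),
             rep("test", cspec$n_test_controls + cspec$n_test_patients))
  groups <- c(rep("control", cspec$n_templates - n_tpat),
              rep("patient", n_tpat),
              rep("control", cspec$n_test_controls),
              rep("patient", cspec$n_test_patients))
  ids <- sprintf("%s%03d", ifelse(roles == "template", "tpl", "sub"),
                 seq_len(total))

  subject_of <- function(i) {
    sp <- cspec$spec
    if (groups[i] == "patient") sp$atrophy <- cspec$atrophy
    ph <- make_phantom(sp, seeds[i], surface_level = cspec$surface_level)
    list(id = ids[i], group = groups[i], seed = seeds[i],
         volume = normalize_subject(ph), label = ph$label,
         surface = ph$surface)
  }

  templates <- list(); tests <- list()
  for (i in seq_len(total)) {
    s <- subject_of(i)
    if (roles[i] == "template") {
      tpl <- make_template(s$id, s$volume, s$label, s$surface)
      attr(tpl, "group") <- s$group
      templates[[length(templates) + 1L]] <- tpl
    } else {
      tests[[length(tests) + 1L]] <- s
    }
  }

  manifest <- tibble::tibble(id = ids, role = roles, group = groups,
                             seed = seeds, master_seed = cspec$seed)
  library <- if (length(templates) >= 2) template_library(templates) else NULL
  if (cspec$n_templates == 1) stop("template library needs N >= 2 templates")
  list(library = library, tests = tests, manifest = manifest,
       spec = cspec)
}

#' Write a cohort to disk (NIfTI + OBJ bundles + manifest)
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in cohort$library$templates) {
    base <- file.path(dir, t$id)
    write_volume(t$volume, paste0(base, "_t1.nii.gz"))
    write_volume(t$label, paste0(base, "_label.nii.gz"))
    write_surface_bundle(t$surface, paste0(base, "_surface"))
  }
  for (s in cohort$tests) {
    base <- file.path(dir, s$id)
    write_volume(s$volume, paste0(base, "_t1.nii.gz"))
    write_volume(s$label, paste0(base, "_truth.nii.gz"))
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
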