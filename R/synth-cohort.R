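# Synthetic patient cohorts with per-patient random effects.

#' Simulate a control/COPD/IPF cohort
#'
#' One section per synthetic patient. Patient-level biological variability is
#' a log-normal multiplicative random effect (median 1, coefficient of
#' variation `patient_cv`) applied to all mRNA medians and, independently, to
#' all protein medians of that patient, so patient means vary realistically
#' around the group presets. Deterministic for a fixed seed.
#'
#' @param presets named list of [group_preset()] objects (defaults to
#'   [default_presets()]).
#' @param n_patients named integer vector of patients per group; default
#'   `c(control = 9, copd = 10, ipf = 6)`, the study-design group sizes.
#' @param seed RNG seed.
#' @param width_um,height_um per-patient section dimensions.
#' @param imaging an [imaging_params()].
#' @param patient_cv coefficient of variation of the patient random effect.
#' @param keep_images keep every rendered [multiplex_image()] in the bundle
#'   (memory-hungry for large cohorts); ground truth and layouts are always
#'   kept.
#' @param callback optional `function(section, patient_id, group)` invoked on
#'   each rendered section before its image is (optionally) dropped; returned
#'   values are collected in `$results`. Lets pipelines stream a cohort
#'   without holding all images in memory.
#' @return Object of class `synthetic_cohort`: list with `patients` (tibble:
#'   patient_id, group, shifts), `truth` (row-bound planted-cell tables),
#'   `layouts`, and optionally `sections`, `results`.
#' @export
simulate_cohort <- function(presets = default_presets(),
                            n_patients = c(control = 9, copd = 10, ipf = 6),
                            seed = 1, width_um = 1200, height_um = 1200,
                            imaging = imaging_params(), patient_cv = 0.25,
                            keep_images = TRUE, callback = NULL) {
  if (any(n_patients < 2)) abort("need at least 2 patients per group")
  if (!all(names(n_patients) %in% names(presets))) {
    abort("every group in n_patients needs a preset of the same name")
  }
  sigma_p <- sqrt(log(1 + patient_cv^2))

  with_seed(seed, {
    patients <- list(); truths <- list(); layouts <- list()
    sections <- list(); results <- list()
    idx <- 0L
    for (g in names(n_patients)) {
      for (j in seq_len(n_patients[[g]])) {
        idx <- idx + 1L
        pid <- sprintf("%s_%02d", g, j)
        u_mrna <- rlnorm(1, 0, sigma_p)
        u_protein <- rlnorm(1, 0, sigma_p)
        seed_layout <- sample.int(.Machine$integer.max, 1)
        seed_section <- sample.int(.Machine$integer.max, 1)
        layout <- make_compartment_layout(width_um, height_um, seed_layout)
        sec <- simulate_section(layout, presets[[g]], imaging, seed_section,
                                mrna_shift = u_mrna, protein_shift = u_protein,
                                patient_id = pid, section_id = pid)
        sec$truth$group <- g
        patients[[idx]] <- tibble::tibble(patient_id = pid, group = g,
                                          u_mrna = u_mrna, u_protein = u_protein)
        truths[[idx]] <- sec$truth
        layouts[[pid]] <- layout
        if (!is.null(callback)) results[[pid]] <- callback(sec, pid, g)
        if (keep_images) sections[[pid]] <- sec
      }
    }
    out <- list(patients = dplyr::bind_rows(patients),
                truth = dplyr::bind_rows(truths),
                layouts = layouts)
    if (keep_images) out$sections <- sections
    if (!is.null(callback)) out$results <- results
    structure(out, class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%s), %d planted cells\n",
              nrow(x$patients),
              paste(sprintf("%s: %d", names(table(x$patients$group)),
                            table(x$patients$group)), collapse = ", "),
              nrow(x$truth)))
  invisible(x)
}

#' Run the full imaging pipeline on a synthetic cohort
#'
#' Streams a synthetic cohort through segmentation, quantification,
#' compartment assignment and per-patient summarisation without retaining
#' images, and returns measured cells, patient summaries and planted truth
#' side by side.
#'
#' @inheritParams simulate_cohort
#' @param config a [study_config()].
#' @return List with `cells` (measured cell table), `summaries` (per-patient
#'   per-compartment tibble with `group`), `truth`, `patients`.
#' @export
run_study <- function(presets = default_presets(),
                      n_patients = c(control = 9, copd = 10, ipf = 6),
                      seed = 1, config = study_config(),
                      width_um = 1200, height_um = 1200,
                      imaging = imaging_params(), patient_cv = 0.25) {
  co <- simulate_cohort(presets, n_patients, seed, width_um, height_um,
                        imaging, patient_cv, keep_images = FALSE,
                        callback = function(sec, pid, g) {
                          cells <- quantify_section(sec$image, sec$layout, config,
                                                    patient_id = pid,
                                                    section_id = pid)
                          summary <- summarize_patient(cells, sec$layout, group = g)
                          list(cells = cells, summary = summary)
                        })
  cells <- dplyr::bind_rows(lapply(co$results, `[[`, "cells"))
  summaries <- dplyr::bind_rows(lapply(co$results, `[[`, "summary"))
  list(cells = cells, summaries = summaries, truth = co$truth,
       patients = co$patients)
}
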