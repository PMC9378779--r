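# Cohort report: per-compartment group descriptives, pairwise tests versus
# control, and Spearman correlation matrices against patient covariates.

REPORT_MEASURES <- c("mean_mrna_corr", "mean_protein_corr", "mean_quotient",
                     "density_cells_per_mm2", "frac_mrna_high",
                     "frac_protein_high")

#' Assemble a cohort report
#'
#' For every compartment x measure: group medians and IQRs, and a two-sided
#' Mann-Whitney test of each non-control group against the control group
#' with star annotations (patients, not cells, are the inference unit). When
#' three or more groups are present a Kruskal-Wallis omnibus with Dunn
#' post-hoc is added. Patient-level Spearman correlations are computed
#' between all pairs of numeric patient columns (the per-compartment
#' measures, plus any supplied covariates such as immune-cell fractions or
#' spirometry values).
#'
#' @param summaries patient-summary tibble ([summarize_patient()] rows for
#'   every patient, with a `group` column).
#' @param config a [study_config()].
#' @param covariates optional tibble with `patient_id` and free numeric
#'   columns.
#' @param control name of the reference group (default `"control"`).
#' @return Object of class `cohort_report`: `group_stats`, `tests`,
#'   `omnibus`, `correlations` (long tibble) and `cor_matrix`.
#' @export
cohort_report <- function(summaries, config = study_config(),
                          covariates = NULL, control = "control") {
  if (!all(c("patient_id", "group", "compartment") %in% names(summaries))) {
    abort("summaries must carry patient_id, group and compartment columns")
  }
  groups <- unique(summaries$group)
  measures <- intersect(REPORT_MEASURES, names(summaries))

  long <- tidyr::pivot_longer(
    summaries[, c("patient_id", "group", "compartment", measures)],
    dplyr::all_of(measures), names_to = "measure", values_to = "value")

  group_stats <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$compartment, .data$measure, .data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     median = median(.data$value),
                     iqr_low = quantile(.data$value, 0.25),
                     iqr_high = quantile(.data$value, 0.75),
                     mean = mean(.data$value),
                     .groups = "drop")

  tests <- NULL
  omnibus <- NULL
  if (length(groups) >= 2 && control %in% groups) {
    cases <- expand.grid(compartment = unique(long$compartment),
                         measure = unique(long$measure),
                         group = setdiff(groups, control),
                         stringsAsFactors = FALSE)
    tests <- dplyr::bind_rows(lapply(seq_len(nrow(cases)), function(i) {
      sub <- long[long$compartment == cases$compartment[i] &
                    long$measure == cases$measure[i], ]
      a <- sub$value[sub$group == cases$group[i]]
      ctrl <- sub$value[sub$group == control]
      a <- a[!is.na(a)]; ctrl <- ctrl[!is.na(ctrl)]
      if (length(a) < 3 || length(ctrl) < 3) return(NULL)
      mw <- mann_whitney(a, ctrl)
      tibble::tibble(compartment = cases$compartment[i],
                     measure = cases$measure[i],
                     group = cases$group[i], control = control,
                     n = length(a), n_control = length(ctrl),
                     u = mw$statistic, p_value = mw$p_value,
                     stars = mw$stars)
    }))
    if (length(groups) >= 3) {
      omni_cases <- unique(long[, c("compartment", "measure")])
      omnibus <- dplyr::bind_rows(lapply(seq_len(nrow(omni_cases)), function(i) {
        sub <- long[long$compartment == omni_cases$compartment[i] &
                      long$measure == omni_cases$measure[i], ]
        gl <- split(sub$value[!is.na(sub$value)], sub$group[!is.na(sub$value)])
        gl <- gl[lengths(gl) >= 3]
        if (length(gl) < 3) return(NULL)
        kd <- kruskal_dunn(gl, adjust = config$dunn_adjust)
        tibble::tibble(compartment = omni_cases$compartment[i],
                       measure = omni_cases$measure[i],
                       h = kd$h, df = kd$df, p_value = kd$p_value,
                       pairwise = list(kd$pairwise))
      }))
    }
  }

  # patient-level wide table for correlations
  wide <- tidyr::pivot_wider(long,
                             names_from = c("compartment", "measure"),
                             values_from = "value")
  if (!is.null(covariates)) {
    wide <- dplyr::left_join(wide, covariates, by = "patient_id")
  }
  numcols <- names(wide)[vapply(wide, is.numeric, logical(1))]
  correlations <- NULL
  cor_matrix <- NULL
  if (length(numcols) >= 2) {
    cor_matrix <- matrix(NA_real_, length(numcols), length(numcols),
                         dimnames = list(numcols, numcols))
    diag(cor_matrix) <- 1
    rows <- list()
    for (i in seq_along(numcols)) {
      for (j in seq_along(numcols)) {
        if (j <= i) next
        x <- wide[[numcols[i]]]; y <- wide[[numcols[j]]]
        ok <- complete.cases(x, y)
        if (sum(ok) < 5 || length(unique(x[ok])) < 2 ||
            length(unique(y[ok])) < 2) next
        sc <- spearman_cor(x, y)
        cor_matrix[i, j] <- cor_matrix[j, i] <- sc$r
        rows[[length(rows) + 1]] <- tibble::tibble(
          var_a = numcols[i], var_b = numcols[j],
          r = sc$r, p_value = sc$p_value, n = sc$n, stars = sc$stars)
      }
    }
    correlations <- dplyr::bind_rows(rows)
  }

  structure(list(group_stats = group_stats, tests = tests, omnibus = omnibus,
                 correlations = correlations, cor_matrix = cor_matrix,
                 control = control),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d descriptive rows, %s pairwise tests vs '%s'\n",
              nrow(x$group_stats),
              if (is.null(x$tests)) "no" else nrow(x$tests), x$control))
  if (!is.null(x$tests)) {
    sig <- x$tests[x$tests$stars != "ns", ]
    if (nrow(sig)) {
      cat("significant vs control:\n")
      print(sig[, c("compartment", "measure", "group", "p_value", "stars")])
    }
  }
  invisible(x)
}

#' Write a cohort report to CSV files and plots
#'
#' @param report a [cohort_report()].
#' @param summaries the patient summaries the report was built from (used
#'   for the plots).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, summaries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$group_stats, file.path(dir, "group_stats.csv"))
  if (!is.null(report$tests)) {
    readr::write_csv(report$tests, file.path(dir, "tests_vs_control.csv"))
  }
  if (!is.null(report$correlations)) {
    readr::write_csv(report$correlations, file.path(dir, "correlations.csv"))
  }
  for (m in unique(report$group_stats$measure)) {
    p <- plot_group_measure(summaries, m)
    ggplot2::ggsave(file.path(dir, paste0(m, ".png")), p,
                    width = 7, height = 4, dpi = 150)
  }
  invisible(dir)
}
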