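#' Bundled example cohort of registration accuracy metrics
#'
#' Per-session accuracy metrics from a five-patient helical-tomotherapy
#' lung evaluation (three MVCT sessions per patient, 15 registrations):
#' landmark target registration errors, per-lung volume/centroid/Jaccard
#' correspondence indices, border-trimmed correlation coefficients, and
#' the left-lung volumes (cm^3) of one illustrative session.  The loader
#' is pure data — every aggregate in the package is recomputed from these
#' per-session rows.
#'
#' @return A list of tibbles: `tre` (patient, session, stage, n_marks,
#'   tre_mean/sd/max in mm), `lung` (per lung: ve_percent, ce_mm, jac),
#'   `cc`, and `volumes` (cm^3).
#' @export
reference_cohort <- function() {
  path <- function(f) system.file("extdata", f, package = "mvctreg",
                                  mustWork = TRUE)
  list(tre = tibble::as_tibble(read.csv(path("cohort_tre.csv"))),
       lung = tibble::as_tibble(read.csv(path("cohort_lung.csv"))),
       cc = tibble::as_tibble(read.csv(path("cohort_cc.csv"))),
       volumes = tibble::as_tibble(read.csv(path("cohort_volumes.csv"))))
}

#' Aggregate per-session metrics into a cohort table
#'
#' Recomputes every cohort-level summary from per-session rows: per-patient
#' TRE (mean and sample SD of the session means, maximum of the session
#' maxima, per stage), the overall CC mean +/- SD per stage, and the cohort
#' means of |V_E|, C_E and JAC pooled over both lungs and all sessions.
#' Rigid-vs-elastic differences are tested per metric with the paired
#' Wilcoxon signed-rank test (pairs: patient x session, or
#' patient x session x lung for the lung metrics); the test is skipped
#' with a notice when fewer than 5 pairs are available.
#'
#' @param cohort a list with tibbles `tre`, `lung` and `cc` as returned by
#'   [reference_cohort()] or [run_cohort()] (any element may be `NULL`).
#' @return A `cohort_table`: list of tibbles `tre_by_patient`,
#'   `cc_summary`, `lung_summary`, `wilcoxon`.
#' @export
aggregate_cohort <- function(cohort) {
  tre_by_patient <- cc_summary <- lung_summary <- NULL
  wil <- list()

  if (!is.null(cohort$tre)) {
    tre_by_patient <- cohort$tre |>
      dplyr::group_by(.data$patient, .data$stage) |>
      dplyr::summarise(n_sessions = dplyr::n(),
                       mean_of_means = mean(.data$tre_mean),
                       sd_of_means = sd(.data$tre_mean),
                       max_of_max = max(.data$tre_max), .groups = "drop") |>
      dplyr::rename(tre_mean = "mean_of_means", tre_sd = "sd_of_means",
                    tre_max = "max_of_max")
    wil$tre_mean <- paired_wilcoxon(cohort$tre, "tre_mean",
                                    c("patient", "session"))
    wil$tre_max <- paired_wilcoxon(cohort$tre, "tre_max",
                                   c("patient", "session"))
  }
  if (!is.null(cohort$cc)) {
    cc_summary <- cohort$cc |>
      dplyr::group_by(.data$stage) |>
      dplyr::summarise(n = dplyr::n(), cc_mean = mean(.data$cc),
                       cc_sd = sd(.data$cc), .groups = "drop")
    wil$cc <- paired_wilcoxon(cohort$cc, "cc", c("patient", "session"))
  }
  if (!is.null(cohort$lung)) {
    lung_summary <- cohort$lung |>
      dplyr::group_by(.data$stage) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_abs_ve = mean(abs(.data$ve_percent)),
                       mean_ce = mean(.data$ce_mm),
                       mean_jac = mean(.data$jac), .groups = "drop")
    keys <- c("patient", "session", "lung")
    wil$abs_ve <- paired_wilcoxon(
      dplyr::mutate(cohort$lung, abs_ve = abs(.data$ve_percent)),
      "abs_ve", keys)
    wil$ce <- paired_wilcoxon(cohort$lung, "ce_mm", keys)
    wil$jac <- paired_wilcoxon(cohort$lung, "jac", keys)
  }
  wilcoxon <- dplyr::bind_rows(lapply(names(wil), function(m) {
    w <- wil[[m]]
    if (is.null(w)) return(NULL)
    tibble::tibble(metric = m, p_value = w$p_value, statistic = w$statistic,
                   n = w$n, method = w$method)
  }))
  structure(list(tre_by_patient = tre_by_patient, cc_summary = cc_summary,
                 lung_summary = lung_summary, wilcoxon = wilcoxon),
            class = "cohort_table")
}

# pair rigid/elastic values of one metric by key columns
paired_wilcoxon <- function(df, metric, keys) {
  wide <- df |>
    dplyr::select(dplyr::all_of(c(keys, "stage", metric))) |>
    tidyr::pivot_wider(names_from = "stage", values_from = dplyr::all_of(metric))
  if (!all(c("rigid", "elastic") %in% names(wide))) return(NULL)
  wide <- wide[stats::complete.cases(wide[, c("rigid", "elastic")]), ]
  if (nrow(wide) < 5L) {
    message(sprintf("Wilcoxon for %s skipped: only %d complete pairs",
                    metric, nrow(wide)))
    return(NULL)
  }
  tryCatch(wilcoxon_signed_rank(wide$rigid, wide$elastic),
           error = function(e) {
             message(sprintf("Wilcoxon for %s skipped: %s", metric,
                             conditionMessage(e)))
             NULL
           })
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table>\n")
  if (!is.null(x$cc_summary)) {
    cat("  CC: ")
    for (i in seq_len(nrow(x$cc_summary)))
      cat(sprintf("%s %.2f +/- %.2f  ", x$cc_summary$stage[i],
                  x$cc_summary$cc_mean[i], x$cc_summary$cc_sd[i]))
    cat("\n")
  }
  if (!is.null(x$lung_summary)) {
    for (i in seq_len(nrow(x$lung_summary)))
      cat(sprintf("  lungs (%s): |V_E| %.2f%%, C_E %.2f mm, JAC %.2f\n",
                  x$lung_summary$stage[i], x$lung_summary$mean_abs_ve[i],
                  x$lung_summary$mean_ce[i], x$lung_summary$mean_jac[i]))
  }
  if (!is.null(x$wilcoxon) && nrow(x$wilcoxon) > 0) {
    cat("  Wilcoxon rigid vs elastic:",
        paste(sprintf("%s p=%.2g", x$wilcoxon$metric, x$wilcoxon$p_value),
              collapse = ", "), "\n")
  }
  invisible(x)
}
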