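#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-landmark registration errors
#' @param x a `tre` object.
#' @param ... unused.
#' @return A tibble with one row per landmark.
#' @export
tidy.tre <- function(x, ...) x$per_landmark

#' @rdname tidy.tre
#' @export
glance.tre <- function(x, ...) {
  tibble::tibble(n = x$n, tre_mean = x$mean, tre_sd = x$sd, tre_max = x$max)
}

#' Tidy the metrics of one registration study
#' @param x a `study_result`.
#' @param ... unused.
#' @return A long tibble: stage, metric, lung (NA for global metrics),
#'   value.
#' @export
tidy.study_result <- function(x, ...) {
  out <- list()
  m <- x$metrics
  out$cc <- dplyr::mutate(m$cc, metric = "cc", lung = NA_character_,
                          value = .data$cc, .keep = "none",
                          stage = m$cc$stage)
  if (!is.null(m$tre))
    out$tre <- m$tre |>
      tidyr::pivot_longer(c("tre_mean", "tre_sd", "tre_max"),
                          names_to = "metric", values_to = "value") |>
      dplyr::transmute(stage = .data$stage, metric = .data$metric,
                       lung = NA_character_, value = .data$value)
  if (!is.null(m$lung))
    out$lung <- m$lung |>
      tidyr::pivot_longer(c("ve_percent", "ce_mm", "jac"),
                          names_to = "metric", values_to = "value") |>
      dplyr::transmute(stage = .data$stage, metric = .data$metric,
                       lung = .data$lung, value = .data$value)
  dplyr::bind_rows(out)
}

#' @rdname tidy.study_result
#' @export
glance.study_result <- function(x, ...) {
  m <- x$metrics
  cc <- setNames(m$cc$cc, m$cc$stage)
  out <- tibble::tibble(patient = x$patient, session = x$session,
                        cc_rigid = cc[["rigid"]], cc_elastic = cc[["elastic"]])
  if (!is.null(m$tre)) {
    tr <- setNames(m$tre$tre_mean, m$tre$stage)
    out$tre_rigid <- tr[["rigid"]]
    out$tre_elastic <- tr[["elastic"]]
  }
  if (!is.null(m$lung)) {
    for (s in c("rigid", "elastic")) {
      sub <- m$lung[m$lung$stage == s, ]
      out[[paste0("jac_", s)]] <- mean(sub$jac)
      out[[paste0("abs_ve_", s)]] <- mean(abs(sub$ve_percent))
    }
  }
  out
}

#' Tidy a cohort table
#' @param x a `cohort_table`.
#' @param ... unused.
#' @return A long tibble of cohort-level summaries.
#' @export
tidy.cohort_table <- function(x, ...) {
  out <- list()
  if (!is.null(x$cc_summary))
    out$cc <- x$cc_summary |>
      tidyr::pivot_longer(c("cc_mean", "cc_sd"), names_to = "metric",
                          values_to = "value") |>
      dplyr::transmute(stage = .data$stage, metric = .data$metric,
                       value = .data$value)
  if (!is.null(x$lung_summary))
    out$lung <- x$lung_summary |>
      tidyr::pivot_longer(c("mean_abs_ve", "mean_ce", "mean_jac"),
                          names_to = "metric", values_to = "value") |>
      dplyr::transmute(stage = .data$stage, metric = .data$metric,
                       value = .data$value)
  dplyr::bind_rows(out)
}

#' Display an axial slice of a volume
#'
#' @param object an [image_volume()].
#' @param slice slice index (middle slice when `NULL`).
#' @param axis slicing axis (default 3, axial).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.image_volume <- function(object, slice = NULL, axis = 3L, ...) {
  d <- img_dim(object)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  sl <- switch(axis, object$voxels[slice, , ], object$voxels[, slice, ],
               object$voxels[, , slice])
  ax <- setdiff(1:3, axis)
  df <- expand.grid(
    x = object$origin[ax[1]] + (seq_len(dim(sl)[1]) - 1) * object$spacing[ax[1]],
    y = object$origin[ax[2]] + (seq_len(dim(sl)[2]) - 1) * object$spacing[ax[2]])
  df$hu <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "HU") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm",
                  title = sprintf("%s slice %d", object$modality, slice)) +
    ggplot2::theme_minimal()
}

#' Difference image between fixed and registered volumes
#'
#' Mirrors the usual visual check of registration quality: darker means
#' better matching.
#'
#' @param fixed,registered [image_volume()]s on the same geometry.
#' @param slice axial slice index (middle when `NULL`).
#' @return A ggplot object.
#' @export
plot_difference <- function(fixed, registered, slice = NULL) {
  stopifnot_image(fixed)
  stopifnot_image(registered)
  diffimg <- image_volume(abs(fixed$voxels - registered$voxels),
                          fixed$spacing, fixed$origin, "synthetic")
  p <- autoplot.image_volume(diffimg, slice = slice)
  p + ggplot2::labs(title = "absolute difference (HU)")
}

#' Per-stage metric comparison for a phantom validation report
#'
#' @param report the `report` tibble of [run_phantom_validation()].
#' @return A ggplot object comparing rigid and elastic stages.
#' @export
plot_validation_report <- function(report) {
  long <- report |>
    tidyr::pivot_longer(c("gt_tre_mean", "cc", "mean_abs_ve", "mean_ce",
                          "mean_jac"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$value,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "stage")
}
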