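#' Plot calibration curves with their fitted lines
#'
#' @param calibration Calibration points (`peptide_id`, `spike_conc`,
#'   `hl_ratio`).
#' @param curves `response_curves` tibble.
#' @param peptides Optional subset of peptide ids.
#' @return A ggplot: log-log scatter of replicate H/L ratios with the
#'   fitted response line and the LOD/LOQ levels marked.
#' @export
plot_response_curves <- function(calibration, curves, peptides = NULL) {
  check_columns(calibration, c("peptide_id", "spike_conc", "hl_ratio"),
                "calibration table")
  if (!is.null(peptides)) {
    calibration <- dplyr::filter(calibration,
                                 .data$peptide_id %in% peptides)
    curves <- dplyr::filter(curves, .data$peptide_id %in% peptides)
  }
  pts <- dplyr::filter(calibration, .data$spike_conc > 0)
  pred <- curves |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(pts, .data$peptide_id),
                       xmin = min(.data$spike_conc),
                       xmax = max(.data$spike_conc), .groups = "drop"),
      by = "peptide_id") |>
    dplyr::rowwise() |>
    dplyr::reframe(peptide_id = .data$peptide_id,
                   spike_conc = exp(seq(log(.data$xmin), log(.data$xmax),
                                        length.out = 50)),
                   hl_ratio = .data$slope * .data$spike_conc +
                     .data$intercept)
  ggplot2::ggplot(pts, ggplot2::aes(.data$spike_conc, .data$hl_ratio)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::geom_vline(data = curves,
                        ggplot2::aes(xintercept = .data$lod),
                        linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_vline(data = curves,
                        ggplot2::aes(xintercept = .data$loq),
                        linetype = "dashed", na.rm = TRUE) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~peptide_id, scales = "free") +
    ggplot2::labs(x = "Heavy spike (amol/µg)",
                  y = "H/L peak-area ratio",
                  title = "SRM response curves",
                  subtitle = "dotted: LOD, dashed: LOQ")
}

#' @exportS3Method ggplot2::autoplot
autoplot.response_curves <- function(object, calibration, ...) {
  plot_response_curves(calibration, object, ...)
}

#' Step plot of a Kaplan-Meier estimate
#'
#' @param object A `km_curve` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot survival step function with the confidence band.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, estimate = 1, ci_low = 1, ci_high = 1),
    object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_low), linetype = "dotted",
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_high),
                       linetype = "dotted", na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  title = "Kaplan-Meier estimate")
}

#' Scree plot of the marker panel screen
#'
#' @param object A `panel_pca` from [pca_panel_screen()].
#' @param ... Unused.
#' @return A ggplot of component eigenvalues with the retention line at 1.
#' @exportS3Method ggplot2::autoplot
autoplot.panel_pca <- function(object, ...) {
  d <- dplyr::mutate(object$eigenvalues,
                     component = factor(.data$component,
                                        levels = .data$component))
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$eigenvalue,
                                  group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$retained), size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Eigenvalue",
                  colour = "Eigenvalue > 1",
                  title = "Principal-component panel screen")
}

#' Classifier score distributions by outcome with the decision threshold
#'
#' @param scored Tibble with `score` and an outcome column.
#' @param outcome Outcome column name.
#' @param threshold Optional decision threshold (0-100 scale).
#' @return A ggplot of score densities per class.
#' @export
plot_score_distribution <- function(scored, outcome, threshold = NULL) {
  check_columns(scored, c("score", outcome), "scored data")
  p <- ggplot2::ggplot(scored,
                       ggplot2::aes(.data$score,
                                    fill = factor(.data[[outcome]]))) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::coord_cartesian(xlim = c(0, 100)) +
    ggplot2::labs(x = "Classifier score (0-100)", y = "Density",
                  fill = "Outcome",
                  title = "Panel classifier score by outcome")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
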