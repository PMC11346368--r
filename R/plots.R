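#' Scatter plot of CCTA vs IVUS volumes with regression line
#'
#' @param matched a `matched_lesions` tibble (or `study_result`).
#' @param measure measure stem (`"tpv"`, `"cp"`, `"ncp"`, `"lap"`,
#'   `"lumen"`, `"vessel"`).
#' @return a ggplot.
#' @export
plot_correlation <- function(matched, measure = "tpv") {
  if (inherits(matched, "study_result")) matched <- matched$lesions
  x <- matched[[paste0("ivus_", measure, "_mm3")]]
  y <- matched[[paste0("ccta_", measure, "_mm3")]]
  pf <- pearson_with_fit(x, y)
  ggplot2::ggplot(tibble(x = x, y = y), ggplot2::aes(x, y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("IVUS %s (mm³)", toupper(measure)),
      y = sprintf("CCTA %s (mm³)", toupper(measure)),
      title = sprintf("%s: r = %.2f, slope = %.2f, intercept = %.2f",
                      toupper(measure), pf$r, pf$slope, pf$intercept)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot with limits of agreement
#'
#' @inheritParams plot_correlation
#' @return a ggplot.
#' @export
plot_bland_altman <- function(matched, measure = "tpv") {
  if (inherits(matched, "study_result")) matched <- matched$lesions
  x <- matched[[paste0("ivus_", measure, "_mm3")]]
  y <- matched[[paste0("ccta_", measure, "_mm3")]]
  ba <- bland_altman(x, y)
  ggplot2::ggplot(tibble(m = (x + y) / 2, d = y - x),
                  ggplot2::aes(.data$m, .data$d)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("Mean of methods, %s (mm³)", toupper(measure)),
      y = "CCTA - IVUS (mm³)",
      title = sprintf("%s: bias %.2f mm³, LoA [%.2f, %.2f]",
                      toupper(measure), ba$mean_diff, ba$loa_low,
                      ba$loa_high)) +
    ggplot2::theme_minimal()
}

#' ROC curves for LAP presence
#'
#' @param report an [agreement_report()] (or `study_result`); alternatively
#'   pass raw vectors to [lap_presence_analysis()] first.
#' @return a ggplot faceted by IVUS threshold.
#' @export
plot_lap_roc <- function(report) {
  if (inherits(report, "study_result")) report <- report$report
  d <- report$data
  if (is.null(d)) abort("report carries no per-lesion data")
  ths <- unique(report$lap$threshold_mm3)
  pts <- purrr::map(ths, function(th) {
    roc <- roc_points(d$ivus_lap_mm3 >= th, d$ccta_lap_mm3)
    roc$threshold <- sprintf("IVUS ≥ %g mm³", th)
    roc
  }) |> bind_rows()
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::facet_wrap(~threshold) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "LAP presence: CCTA vs IVUS thresholds") +
    ggplot2::theme_minimal()
}

#' Lumen/vessel area profiles of a pullback or cross-section series
#'
#' @param profile a `pullback_profile` or `cross_sections` tibble.
#' @return a ggplot.
#' @export
plot_area_profile <- function(profile) {
  pos <- if ("station_mm" %in% names(profile)) "station_mm" else "s_mm"
  d <- tidyr::pivot_longer(
    as_tibble(profile)[c(pos, "lumen_area_mm2", "vessel_area_mm2")],
    -1, names_to = "series", values_to = "area")
  ggplot2::ggplot(d, ggplot2::aes(.data[[pos]], .data$area,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position (mm)", y = "Area (mm²)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.agreement_report <- function(object, measure = "tpv", ...) {
  plot_correlation(object$data, measure)
}

#' @export
autoplot.study_result <- function(object, measure = "tpv", ...) {
  plot_correlation(object$lesions, measure)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
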