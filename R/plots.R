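## ggplot2 presentation layer. Each result type gets an autoplot() method;
## plot_cohort_panels() reproduces the paired boxplot panel convention.

#' @export
#' @rdname autoplot-nasoair
#' @param object A result object (`geometry_profile`, `resistance_profile`,
#'   `regional_partition` or `cohort_comparison`).
#' @param ... Unused.
#' @name autoplot-nasoair
#' @title Plot methods for pipeline results
#' @description Quick-look ggplot2 plots: CSA/perimeter profiles along the
#'   normalized centerline, cumulative resistance curves, regional
#'   flow/WSS-fraction bands, and paired cohort boxplots.
autoplot.geometry_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_norm, y = .data$area_m2 * 1e4)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::labs(
      x = "normalized centerline distance",
      y = expression("cross-sectional area" ~ (cm^2)),
      title = "Bilateral cross-sectional area profile"
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname autoplot-nasoair
autoplot.resistance_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_norm, y = .data$Rcum_Pa_s_per_ml)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(
      x = "normalized centerline distance",
      y = expression("cumulative resistance" ~ (Pa %.% s %.% ml^-1)),
      title = "Cumulative trans-nasal resistance"
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname autoplot-nasoair
autoplot.regional_partition <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(-"s_norm", names_to = c("what", "region"),
                        names_pattern = "frac_(flow|wss)_(.*)") |>
    dplyr::mutate(what = dplyr::recode(.data$what, flow = "mass flow",
                                       wss = "WSS loading"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s_norm, y = .data$value,
                                     colour = .data$region)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~what, ncol = 1) +
    ggplot2::labs(x = "normalized centerline distance", y = "fraction",
                  colour = NULL,
                  title = "Superior/middle/inferior partitioning") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname autoplot-nasoair
autoplot.cohort_comparison <- function(object, ...) {
  plot_cohort_panels(object)
}

#' Paired cohort boxplot panels
#'
#' One panel per metric, with normal and decongested boxes (box edges at the
#' quartiles, whiskers at the most extreme non-outliers, outliers marked)
#' and the Wilcoxon p-value in the panel strip; an asterisk flags
#' significance at the comparison's alpha.
#'
#' @param comparison A [compare_cohort()] result.
#' @param metrics Optional subset of metric names to plot.
#' @return A ggplot object.
#' @export
plot_cohort_panels <- function(comparison, metrics = NULL) {
  tb <- comparison$cohort
  if (!is.null(metrics)) tb <- tb[tb$metric %in% metrics, ]
  long <- tb |>
    tidyr::pivot_longer(c("value_normal", "value_decongested"),
                        names_to = "state", values_to = "value") |>
    dplyr::mutate(state = dplyr::recode(.data$state,
                                        value_normal = "normal",
                                        value_decongested = "decongested"))
  lab <- comparison$tests |>
    dplyr::mutate(panel = sprintf("%s\np = %.3g%s", .data$metric,
                                  .data$p_value,
                                  ifelse(.data$significant, " *", "")))
  long <- dplyr::left_join(long, lab[, c("metric", "panel")], by = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$value,
                                     fill = .data$state)) +
    ggplot2::geom_boxplot(outlier.shape = 4, outlier.colour = "red",
                          show.legend = FALSE) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.7, colour = "red", linewidth = 0.3,
                          show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(normal = "#fddbc7",
                                          decongested = "#d1e5f0")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
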