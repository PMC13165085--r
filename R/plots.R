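#' Mahalanobis divergence series for one plant
#'
#' Median per-pixel MD^2 per day with the assigned change day marked.
#'
#' @param report A `change_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_md_series <- function(report, ...) {
  stopifnot(inherits(report, "change_report"))
  tests <- report$tests
  ggplot2::ggplot(report$md2, ggplot2::aes(x = factor(.data$day), y = .data$md2)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    ggplot2::geom_line(data = tests,
                       ggplot2::aes(x = factor(.data$day), y = .data$median_md2,
                                    group = 1),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = which(tests$day == report$change_day),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "acquisition day", y = expression(MD^2 ~ "(log scale)"),
      title = sprintf("Divergence from day-1 baseline%s",
                      if (is.na(report$plant_id)) "" else
                        paste0(" — ", report$plant_id)),
      subtitle = sprintf("change day %s%s", report$change_day,
                         if (report$defaulted) " (defaulted)" else "")
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot change_report
#' @export
autoplot.change_report <- function(object, ...) plot_md_series(object, ...)

#' Per-plant change days and group means
#'
#' @param monitor A `trial_monitor` (or its `change_days` tibble).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_change_days <- function(monitor, ...) {
  cd <- if (inherits(monitor, "trial_monitor")) monitor$change_days else monitor
  summ <- summarize_groups(cd)
  ggplot2::ggplot(cd, ggplot2::aes(x = .data$plant_id, y = .data$change_day,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = summ,
                        ggplot2::aes(yintercept = .data$mean_raw,
                                     colour = .data$group),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "assigned change day",
                  title = "Change day per vine (dashed: group means)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @method autoplot trial_monitor
#' @export
autoplot.trial_monitor <- function(object, ...) plot_change_days(object, ...)

#' PC1 loadings overlay across plants
#'
#' @param loadings Long tibble (`plant_id`, `wavelength`, `pc1_loading`), as
#'   produced by [run_trial()], or a `trial_monitor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_loadings <- function(loadings, ...) {
  if (inherits(loadings, "trial_monitor")) {
    loadings <- purrr::map_dfr(names(loadings$reports), function(p) {
      m <- loadings$reports[[p]]$model
      tibble::tibble(plant_id = p, wavelength = m$wavelengths,
                     pc1_loading = m$loadings[, 1])
    })
  }
  ggplot2::ggplot(loadings, ggplot2::aes(x = .data$wavelength,
                                         y = .data$pc1_loading,
                                         group = .data$plant_id)) +
    ggplot2::geom_line(alpha = 0.4, colour = "darkgreen") +
    ggplot2::labs(x = "wavelength (nm)", y = "PC1 loading",
                  title = "First-component loadings, one line per vine") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
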