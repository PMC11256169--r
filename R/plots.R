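#' Plot a population time series
#'
#' One line per species showing the across-replicate mean count per timestep,
#' with a ribbon of +/- one standard deviation (the replicate spread).
#'
#' @param object A [run_scenario()] result.
#' @param thin Plot every `thin`-th timestep (keeps the plot light).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skinsim_popts <- function(object, thin = 10, ...) {
  df <- object |>
    dplyr::filter(.data$timestep %% thin == 0) |>
    dplyr::group_by(.data$day, .data$species) |>
    dplyr::summarise(mean = mean(.data$count), sd = sd(.data$count),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$mean,
                                   colour = .data$species,
                                   fill = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = "population (cells)",
                  colour = "species", fill = "species") +
    ggplot2::theme_minimal()
}

#' Plot invader survival times
#'
#' Mean +/- SD of survival across replicates; censored replicates sit at the
#' post-introduction horizon.
#'
#' @param object A [survival_time()] result, or a named list of them (one
#'   entry per condition).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skinsim_survival <- function(object, ...) {
  plot_survival(list(result = object))
}

#' @rdname autoplot.skinsim_survival
#' @param results Named list of [survival_time()] results.
#' @export
plot_survival <- function(results) {
  df <- purrr::imap_dfr(results, function(res, nm) {
    dplyr::mutate(glance(res), condition = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$mean_survival_days)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_survival_days - .data$sd_survival_days,
                   ymax = .data$mean_survival_days + .data$sd_survival_days),
      width = 0.2) +
    ggplot2::labs(x = NULL, y = "invader survival (days)") +
    ggplot2::theme_minimal()
}

#' Plot fluorescence curves
#'
#' @param data A [fluorescence_curves()] table.
#' @return A ggplot object: per-group mean with +/- SD error bars.
#' @export
plot_curves <- function(data) {
  data <- fluorescence_curves(data)
  df <- data |>
    dplyr::group_by(.data$group, .data$time_h) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h / 24, .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.1) +
    ggplot2::labs(x = "day", y = "fluorescence (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}
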