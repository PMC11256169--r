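#' Tidiers for skinsim result objects
#'
#' broom-style methods: `tidy()` returns the per-unit table (per sample, per
#' replicate, per model term), `glance()` a one-row summary.
#'
#' @param x A skinsim result object.
#' @param ... Unused.
#' @return A tibble.
#' @name skinsim-tidiers
NULL

#' @rdname skinsim-tidiers
#' @export
tidy.skinsim_curve_stats <- function(x, ...) x$per_sample

#' @rdname skinsim-tidiers
#' @export
glance.skinsim_curve_stats <- function(x, ...) {
  tibble::tibble(
    stop_time_days = x$stop_time_days, stop_time_sd = x$stop_time_sd,
    rate_constant = x$rate_constant, n_samples = x$n_samples,
    n_not_reached = x$n_not_reached, n_excluded = x$n_excluded
  )
}

#' @rdname skinsim-tidiers
#' @export
tidy.skinsim_rate_constant <- function(x, ...) x$per_sample

#' @rdname skinsim-tidiers
#' @export
glance.skinsim_rate_constant <- function(x, ...) {
  tibble::tibble(rate_constant = x$rate_constant,
                 n_samples = x$n_samples, n_excluded = x$n_excluded)
}

#' @rdname skinsim-tidiers
#' @export
tidy.skinsim_doubling_fit <- function(x, ...) {
  co <- coef(x$fit)
  tibble::tibble(term = c("log2_y0", "growth_rate_per_min"),
                 estimate = unname(co))
}

#' @rdname skinsim-tidiers
#' @export
glance.skinsim_doubling_fit <- function(x, ...) {
  tibble::tibble(doubling_time = x$doubling_time,
                 window_start = x$window[1], window_end = x$window[2],
                 n_points = x$n_points, r_squared = x$r_squared)
}

#' @rdname skinsim-tidiers
#' @export
glance.skinsim_survival <- function(x, ...) {
  tibble::tibble(
    mean_survival_days = mean(x$survival_days),
    sd_survival_days = if (nrow(x) > 1) sd(x$survival_days) else 0,
    n_replicates = nrow(x),
    n_censored = sum(x$censored),
    horizon_days = attr(x, "horizon_days")
  )
}

#' @rdname skinsim-tidiers
#' @export
glance.skinsim_popts <- function(x, ...) {
  config <- attr(x, "config")
  tibble::tibble(
    n_replicates = dplyr::n_distinct(x$replicate),
    n_species = dplyr::n_distinct(x$species),
    total_timesteps = config$total_timesteps,
    horizon_days = timestep_to_days(config$total_timesteps, config$clock),
    truncated = isTRUE(attr(x, "truncated"))
  )
}
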