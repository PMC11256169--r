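#' Run a scenario across replicates
#'
#' Executes `n_replicates` independent simulations; replicate `r` seeds the
#' random stream with `base_seed + r`, so a given configuration is fully
#' deterministic.  Interventions (including the invader introduction) are
#' applied between timesteps; the count logged at an intervention's timestep
#' reflects the post-intervention state, so the invader count jumps from 0 to
#' the inoculum size at its introduction step.
#'
#' @param config A [scenario_config()].
#' @param stop_after_invader_extinct If `TRUE`, each replicate stops once the
#'   invader has gone extinct after its introduction (the returned series is
#'   then truncated; use only when post-extinction dynamics are not needed,
#'   e.g. for survival statistics).
#' @return A tibble with columns `replicate`, `timestep`, `day`, `species`,
#'   `count` (class `skinsim_popts`), carrying the configuration and the
#'   replicate seeds as attributes.
#' @export
run_scenario <- function(config, stop_after_invader_extinct = FALSE) {
  validate_scenario(config)
  events <- scenario_events(config)
  seeds <- config$base_seed + seq_len(config$n_replicates)
  watch_name <- if (stop_after_invader_extinct && !is.null(config$invader)) {
    config$invader$name
  }

  out <- purrr::map_dfr(seq_len(config$n_replicates), function(r) {
    set.seed(seeds[r])
    state <- init_environment(config)
    stops <- sort(unique(c(
      if (!is.null(events)) events$at_timestep[events$at_timestep > 0],
      config$total_timesteps
    )))
    stops <- stops[stops <= config$total_timesteps]
    if (!is.null(events)) {
      for (i in which(events$at_timestep == 0)) {
        state <- apply_one_intervention(state, events[i, ], config)
      }
    }
    watching <- FALSE
    for (tstop in stops) {
      n <- tstop - state$timestep
      if (n > 0) {
        state <- advance(state, n,
                         watch_species = if (watching) watch_name)
      }
      if (state$timestep < tstop) break  # early extinction stop
      if (!is.null(events)) {
        for (i in which(events$at_timestep == tstop)) {
          state <- apply_one_intervention(state, events[i, ], config)
          if (!is.null(watch_name) &&
              events$kind[i] == "introduce_invader") {
            watching <- TRUE
          }
        }
      }
      if (watching && !is.null(watch_name)) {
        cnt <- count_by_species(state)
        if (cnt[match(watch_name, state$species_names)] == 0) break
      }
    }
    counts <- state$counts_log
    steps <- seq_len(nrow(counts)) - 1L
    tibble::tibble(
      replicate = r,
      timestep = rep(steps, times = ncol(counts)),
      day = timestep_to_days(.data$timestep, config$clock),
      species = rep(colnames(counts), each = length(steps)),
      count = as.integer(counts)
    )
  })

  structure(out,
            class = c("skinsim_popts", class(tibble::tibble()))) |>
    set_popts_attrs(config, seeds,
                    truncated = isTRUE(stop_after_invader_extinct))
}

set_popts_attrs <- function(x, config, seeds, truncated) {
  attr(x, "config") <- config
  attr(x, "seeds") <- seeds
  attr(x, "truncated") <- truncated
  x
}

#' Invader survival time per replicate
#'
#' Survival is the time from introduction to extinction (first timestep after
#' introduction at which the invader count is zero), in days.  A replicate in
#' which the invader is still alive at the simulation horizon is censored and
#' reported at the full post-introduction horizon.
#'
#' @param timeseries A [run_scenario()] result.
#' @param invader_name Invader species; defaults to the configuration's.
#' @return A tibble with columns `replicate`, `survival_days`, `censored`
#'   (class `skinsim_survival`).
#' @export
survival_time <- function(timeseries, invader_name = NULL) {
  config <- attr(timeseries, "config")
  if (is.null(invader_name)) {
    if (is.null(config$invader)) stop("no invader in this scenario", call. = FALSE)
    invader_name <- config$invader$name
  }
  intro <- config$invader_at_timestep
  horizon_days <- timestep_to_days(config$total_timesteps - intro, config$clock)
  spd <- config$clock$steps_per_day

  out <- timeseries |>
    dplyr::filter(.data$species == invader_name, .data$timestep >= intro) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      extinct_at = if (any(.data$count == 0)) {
        min(.data$timestep[.data$count == 0])
      } else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      censored = is.na(.data$extinct_at),
      survival_days = dplyr::if_else(
        .data$censored, horizon_days, (.data$extinct_at - intro) / spd)
    ) |>
    dplyr::select("replicate", "survival_days", "censored")

  structure(out, class = c("skinsim_survival", class(tibble::tibble())),
            horizon_days = horizon_days, invader = invader_name)
}

#' Steady-state community composition
#'
#' Mean relative abundance per species over the trailing `window_days` before
#' the invader introduction (or before the end of the run when the scenario
#' has no invader), computed per replicate and averaged across replicates.
#'
#' @param timeseries A [run_scenario()] result.
#' @param window_days Averaging window in days.
#' @return A tibble with columns `species`, `fraction`, `sd`, `mean_count`.
#' @export
steady_state_fractions <- function(timeseries, window_days = 1.0) {
  config <- attr(timeseries, "config")
  spd <- config$clock$steps_per_day
  ref <- if (!is.null(config$invader)) {
    config$invader_at_timestep - 1L  # exclude the introduction step itself
  } else {
    max(timeseries$timestep)
  }
  lo <- ref - window_days * spd

  per_rep <- timeseries |>
    dplyr::filter(.data$timestep > lo, .data$timestep <= ref) |>
    dplyr::group_by(.data$replicate, .data$species) |>
    dplyr::summarise(mean_count = mean(.data$count), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$mean_count / sum(.data$mean_count)) |>
    dplyr::ungroup()

  per_rep |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      fraction_sd = sd(.data$fraction),
      fraction = mean(.data$fraction),
      mean_count = mean(.data$mean_count),
      .groups = "drop"
    ) |>
    dplyr::select("species", "fraction", sd = "fraction_sd", "mean_count") |>
    dplyr::arrange(dplyr::desc(.data$fraction))
}

#' Mean and standard deviation across replicates
#'
#' @param values Numeric vector, one value per replicate.
#' @return A one-row tibble with columns `mean`, `sd`, `n`.
#' @examples
#' replicate_summary(c(0, 1, 2))
#' @export
replicate_summary <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  tibble::tibble(mean = mean(values),
                 sd = if (length(values) > 1) sd(values) else 0,
                 n = length(values))
}

#' Write a population time series to tidy CSV
#'
#' Columns: `replicate`, `timestep`, `day`, `species`, `count`.
#'
#' @param timeseries A [run_scenario()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(timeseries, path) {
  readr::write_csv(timeseries, path)
  invisible(path)
}
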