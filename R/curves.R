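#' Validate a fluorescence curve table
#'
#' Curves are stored tidily: one row per sample x timepoint with columns
#' `sample`, `group`, `time_h`, `value`.  All samples must share the same
#' strictly increasing grid of at least three timepoints, with no missing
#' values.
#'
#' @param data A data frame with columns `sample`, `group`, `time_h`, `value`.
#' @return `data` as a validated tibble.
#' @export
fluorescence_curves <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("sample", "group", "time_h", "value")
  if (!all(need %in% names(data))) {
    stop("curve data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[need])) stop("curve data contains missing values", call. = FALSE)
  tp <- sort(unique(data$time_h))
  if (length(tp) < 3) stop("need at least 3 timepoints", call. = FALSE)
  counts <- dplyr::count(data, .data$sample)
  if (length(unique(counts$n)) != 1 || unique(counts$n) != length(tp)) {
    stop("all samples must share the same timepoint grid", call. = FALSE)
  }
  data
}

#' Subtract the background group
#'
#' At each timepoint, the mean value of the background (control) group is
#' subtracted from every other sample.  Negative results are kept, not
#' clipped.  Background rows are dropped from the output.
#'
#' @param data A [fluorescence_curves()] table.
#' @param background Group label of the background control.
#' @return The background-subtracted treatment rows.
#' @export
subtract_background <- function(data, background = "PBS") {
  data <- fluorescence_curves(data)
  if (!background %in% data$group) {
    stop("no samples in background group '", background, "'", call. = FALSE)
  }
  bg <- data |>
    dplyr::filter(.data$group == background) |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(bg_mean = mean(.data$value), .groups = "drop")
  data |>
    dplyr::filter(.data$group != background) |>
    dplyr::left_join(bg, by = "time_h") |>
    dplyr::mutate(value = .data$value - .data$bg_mean) |>
    dplyr::select(-"bg_mean")
}

#' Central-difference derivative of a series
#'
#' Interior points use `(y[i+1] - y[i-1]) / (t[i+1] - t[i-1])`; the endpoints
#' use one-sided differences.
#'
#' @param timepoints Strictly increasing numeric vector.
#' @param series Values at `timepoints`.
#' @return Derivative estimates at every timepoint.
#' @examples
#' central_difference(0:2, (0:2)^2)  # exact for quadratics at the interior
#' @export
central_difference <- function(timepoints, series) {
  n <- length(timepoints)
  stopifnot(n == length(series), n >= 2, all(diff(timepoints) > 0))
  d <- numeric(n)
  d[1] <- (series[2] - series[1]) / (timepoints[2] - timepoints[1])
  d[n] <- (series[n] - series[n - 1]) / (timepoints[n] - timepoints[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (series[i + 1] - series[i - 1]) / (timepoints[i + 1] - timepoints[i - 1])
  }
  d
}

#' Time at which production stops
#'
#' Production is considered to have stopped at the first timepoint where the
#' central-difference derivative of the signal is negative.  Only interior
#' timepoints are scanned (the one-sided endpoint derivatives are noisy by
#' construction).  Returns the stop time in days, or `NA` when the derivative
#' never becomes negative (production "not reached" its stop within the
#' observation window).
#'
#' @param timepoints Timepoints in hours.
#' @param series Signal values.
#' @return Stop time in days, or `NA_real_`.
#' @export
production_stop_time <- function(timepoints, series) {
  n <- length(timepoints)
  stopifnot(n == length(series), n >= 3)
  d <- central_difference(timepoints, series)
  interior <- 2:(n - 1)
  hit <- interior[d[interior] < 0]
  if (length(hit) == 0) return(NA_real_)
  timepoints[hit[1]] / 24
}

#' Log-log rate constant of fluorescence curves
#'
#' For each sample, fits an ordinary least-squares line to `log10(value)`
#' versus `log10(time_h)` and reports the slope; the rate constant is the
#' mean slope across samples.  The fit starts at the first timepoint where
#' both time and value are strictly positive; rows with non-positive values
#' inside the fitted range are excluded and counted in `n_excluded`.
#'
#' @param data A [fluorescence_curves()] table (background already
#'   subtracted, if applicable).
#' @return A `skinsim_rate_constant` object; see [tidy()] and [glance()].
#' @examples
#' tp <- 1:10
#' df <- tibble::tibble(sample = "a", group = "t", time_h = tp,
#'                      value = 3 * tp^2)
#' glance(rate_constant(df))$rate_constant  # 2
#' @export
rate_constant <- function(data) {
  data <- fluorescence_curves(data)
  per_sample <- data |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(df, key) {
      ok <- df$time_h > 0 & df$value > 0
      if (sum(ok) < 2) {
        return(tibble::tibble(slope = NA_real_,
                              n_points = sum(ok),
                              n_excluded = sum(df$time_h > 0) - sum(ok)))
      }
      fit <- lm(log10(value) ~ log10(time_h), data = df[ok, ])
      tibble::tibble(slope = unname(coef(fit)[2]), n_points = sum(ok),
                     n_excluded = sum(df$time_h > 0) - sum(ok))
    }) |>
    dplyr::ungroup()
  structure(
    list(per_sample = per_sample,
         rate_constant = mean(per_sample$slope, na.rm = TRUE),
         n_samples = nrow(per_sample),
         n_excluded = sum(per_sample$n_excluded)),
    class = "skinsim_rate_constant"
  )
}

#' @export
print.skinsim_rate_constant <- function(x, ...) {
  cat("Log-log rate constant: ", format(x$rate_constant, digits = 4),
      " (mean of ", x$n_samples, " sample slopes",
      if (x$n_excluded > 0) paste0(", ", x$n_excluded, " points excluded"),
      ")\n", sep = "")
  invisible(x)
}

#' Per-sample curve statistics
#'
#' Computes, for every sample of a (background-subtracted) curve table, the
#' production stop time and the log-log slope, plus ensemble means.
#'
#' @param data A [fluorescence_curves()] table.
#' @return A `skinsim_curve_stats` object; `tidy()` gives the per-sample
#'   table, `glance()` the ensemble summary.
#' @export
curve_stats <- function(data) {
  data <- fluorescence_curves(data)
  rc <- rate_constant(data)
  stops <- data |>
    dplyr::group_by(.data$sample) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(
      stop_time_days = production_stop_time(.data$time_h, .data$value),
      .groups = "drop"
    )
  per_sample <- dplyr::left_join(stops, rc$per_sample, by = "sample")
  structure(
    list(per_sample = per_sample,
         stop_time_days = mean(per_sample$stop_time_days, na.rm = TRUE),
         stop_time_sd = sd(per_sample$stop_time_days, na.rm = TRUE),
         rate_constant = rc$rate_constant,
         n_samples = nrow(per_sample),
         n_not_reached = sum(is.na(per_sample$stop_time_days)),
         n_excluded = rc$n_excluded),
    class = "skinsim_curve_stats"
  )
}

#' @export
print.skinsim_curve_stats <- function(x, ...) {
  cat("Curve statistics over ", x$n_samples, " samples\n", sep = "")
  cat("  production stop: ", format(x$stop_time_days, digits = 3), " +/- ",
      format(x$stop_time_sd, digits = 3), " days",
      if (x$n_not_reached > 0) paste0(" (", x$n_not_reached, " not reached)"),
      "\n", sep = "")
  cat("  rate constant:   ", format(x$rate_constant, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Fit a doubling time to a growth curve
#'
#' Selects the mid-exponential phase as the longest contiguous run of
#' timepoints whose log-absorbance lies between 20% and 80% of the observed
#' log-range, then fits `y = y0 * 2^(t / Td)` by least squares on `log2(y)`.
#'
#' @param timepoints Time in minutes.
#' @param absorbance Positive growth readings (e.g. OD600).
#' @return A `skinsim_doubling_fit` object; `glance()` reports `doubling_time`
#'   in minutes.
#' @examples
#' t <- seq(0, 300, by = 10)
#' glance(fit_doubling_time(t, 0.01 * 2^(t / 30)))$doubling_time  # 30
#' @export
fit_doubling_time <- function(timepoints, absorbance) {
  stopifnot(length(timepoints) == length(absorbance),
            length(timepoints) >= 3, all(diff(timepoints) > 0))
  ok <- absorbance > 0
  t <- timepoints[ok]; y <- absorbance[ok]
  if (length(y) < 3) stop("need at least 3 positive readings", call. = FALSE)
  ly <- log(y)
  lo <- min(ly) + 0.2 * diff(range(ly))
  hi <- min(ly) + 0.8 * diff(range(ly))
  inside <- ly >= lo & ly <= hi
  # longest contiguous run inside the mid-exponential band
  r <- rle(inside)
  if (!any(r$values)) stop("no mid-exponential window found", call. = FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  best <- which.max(ifelse(r$values, r$lengths, 0))
  win <- starts[best]:ends[best]
  if (length(win) < 2) stop("mid-exponential window too short", call. = FALSE)
  fit <- lm(log2(y[win]) ~ t[win])
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stop("no growth detected in the fitted window", call. = FALSE)
  obs <- log2(y[win])
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(doubling_time = 1 / slope,
         window = range(t[win]), n_points = length(win),
         r_squared = r2, fit = fit),
    class = "skinsim_doubling_fit"
  )
}

#' @export
print.skinsim_doubling_fit <- function(x, ...) {
  cat("Doubling time: ", format(x$doubling_time, digits = 4), " min ",
      "(window ", format(x$window[1]), "-", format(x$window[2]), " min, ",
      x$n_points, " points, R^2 = ", format(x$r_squared, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' Generate synthetic plate-reader fluorescence curves
#'
#' Emulates the structure of skin-model plate-reader data: a treatment group
#' whose mean signal rises towards a plateau and declines after a programmed
#' stop time, sitting on a constant background, plus a background-only
#' control group; Gaussian noise is added to every reading.  The treatment
#' mean is
#' `background + plateau * (1 - exp(-rise_rate * t))` for `t <= stop`, and
#' declines as `exp(-decline_rate * (t - stop))` afterwards.
#'
#' @param n_samples Treatment samples.
#' @param n_background Background control samples.
#' @param timepoints_h Measurement grid in hours.
#' @param plateau Plateau fluorescence above background.
#' @param rise_rate Rise rate per hour.
#' @param stop_time_days Programmed production stop, in days.
#' @param decline_rate Post-stop decay rate per hour.
#' @param background Background fluorescence level.
#' @param noise_sd Gaussian noise SD (0 gives the smooth analytic curve).
#' @param seed RNG seed; the same seed reproduces the same data.
#' @param treatment_label,background_label Group labels.
#' @return A tidy curve table as accepted by [fluorescence_curves()].
#' @export
generate_synthetic_curves <- function(n_samples = 8, n_background = 8,
                                      timepoints_h = seq(0, 168, by = 12),
                                      plateau = 10000, rise_rate = 0.05,
                                      stop_time_days = 4, decline_rate = 0.01,
                                      background = 500, noise_sd = 200,
                                      seed = 1,
                                      treatment_label = "BS-GFP",
                                      background_label = "PBS") {
  stopifnot(n_samples >= 1, plateau > 0, rise_rate > 0, stop_time_days > 0,
            decline_rate >= 0, background >= 0, noise_sd >= 0)
  set.seed(seed)
  stop_h <- stop_time_days * 24
  mu <- plateau * (1 - exp(-rise_rate * pmin(timepoints_h, stop_h)))
  mu <- ifelse(timepoints_h > stop_h,
               mu * exp(-decline_rate * (timepoints_h - stop_h)), mu)
  nt <- length(timepoints_h)
  mk <- function(n, label, signal) {
    purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(
        sample = paste0(label, "_", i), group = label,
        time_h = timepoints_h,
        value = background + signal + rnorm(nt, sd = noise_sd)
      )
    })
  }
  dplyr::bind_rows(mk(n_samples, treatment_label, mu),
                   mk(n_background, background_label, 0))
}

#' Generate synthetic power-law curves
#'
#' Samples follow `value = coef * time^exponent` with multiplicative
#' log-normal noise, the regime in which the log-log rate constant is the
#' power-law exponent.
#'
#' @param n_samples Number of samples.
#' @param timepoints_h Measurement grid in hours (positive).
#' @param exponent True power-law exponent.
#' @param coef Multiplicative coefficient.
#' @param noise_sd SD of the log10-scale noise (0 = exact power law).
#' @param seed RNG seed.
#' @return A tidy curve table, group label `"powerlaw"`.
#' @export
generate_power_law_curves <- function(n_samples = 8,
                                      timepoints_h = seq(4, 168, by = 12),
                                      exponent = 0.8, coef = 50,
                                      noise_sd = 0.05, seed = 1) {
  stopifnot(all(timepoints_h > 0), coef > 0, noise_sd >= 0)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_samples), function(i) {
    tibble::tibble(
      sample = paste0("pl_", i), group = "powerlaw",
      time_h = timepoints_h,
      value = coef * timepoints_h^exponent *
        10^rnorm(length(timepoints_h), sd = noise_sd)
    )
  })
}

#' Read/write curve tables as CSV
#'
#' Long format with columns `sample`, `group`, `time_h`, `value`.
#'
#' @param path CSV file path.
#' @return For `read_curves_csv`, a validated curve tibble.
#' @export
read_curves_csv <- function(path) {
  fluorescence_curves(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_curves_csv
#' @param data A curve table.
#' @export
write_curves_csv <- function(data, path) {
  readr::write_csv(fluorescence_curves(data), path)
  invisible(path)
}
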