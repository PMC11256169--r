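#' Model clock
#'
#' One timestep represents `minutes_per_timestep` minutes of real time; at the
#' default of one minute per step a simulated day is 1440 steps, so timestep
#' 4500 corresponds to 3.125 days.
#'
#' @param minutes_per_timestep Minutes of real time per simulation step.
#' @return A `skinsim_clock` list with a `steps_per_day` field.
#' @examples
#' timestep_to_days(4500)  # 3.125
#' @export
model_clock <- function(minutes_per_timestep = 1) {
  stopifnot(minutes_per_timestep > 0)
  structure(
    list(minutes_per_timestep = minutes_per_timestep,
         steps_per_day = 1440 / minutes_per_timestep),
    class = "skinsim_clock"
  )
}

#' @rdname model_clock
#' @param timestep Integer timestep(s).
#' @param clock A `skinsim_clock`.
#' @export
timestep_to_days <- function(timestep, clock = model_clock()) {
  timestep / clock$steps_per_day
}

#' @rdname model_clock
#' @param days Simulated days.
#' @export
days_to_timestep <- function(days, clock = model_clock()) {
  as.integer(round(days * clock$steps_per_day))
}
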