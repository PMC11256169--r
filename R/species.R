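#' Define a nutrient field
#'
#' A nutrient lives on the lattice as a per-patch amount.  Each timestep every
#' patch gains `replenish_rate` units (skin secretion), after which the field
#' is smoothed: a patch keeps `1 - diffusivity` of its content and spreads the
#' rest equally over its eight toroidal neighbours.
#'
#' @param name Nutrient identifier.
#' @param diffusivity Per-step smoothing coefficient in `[0, 1]`.
#' @param replenish_rate Units secreted per patch per timestep (>= 0).
#' @param initial_amount Units per patch at `t = 0` (>= 0).
#' @return A `skinsim_nutrient` list.
#' @examples
#' nutrient("sebum_lipid", replenish_rate = 5)
#' @export
nutrient <- function(name, diffusivity = 0.2, replenish_rate = 0,
                     initial_amount = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(diffusivity) || diffusivity < 0 || diffusivity > 1) {
    stop("`diffusivity` must lie in [0, 1]", call. = FALSE)
  }
  if (replenish_rate < 0) stop("`replenish_rate` must be >= 0", call. = FALSE)
  if (initial_amount < 0) stop("`initial_amount` must be >= 0", call. = FALSE)
  structure(
    list(name = name, diffusivity = diffusivity,
         replenish_rate = replenish_rate, initial_amount = initial_amount),
    class = "skinsim_nutrient"
  )
}

#' Define a bacterial species
#'
#' Species are parameterised by an energy ledger: each agent consumes up to
#' `uptake_rate / (1 + growth_defect)` nutrient units per timestep from the
#' carbon sources it can use, converts them to energy at `yield`, pays
#' `maintenance` every step, divides when its energy reaches
#' `division_threshold` (splitting energy exactly in half), and dies when its
#' energy falls to zero or, with per-step probability `p_kill`, when the local
#' antibiotic concentration is at or above `mic`.
#'
#' If `uptake_rate` is `NULL` it is filled in by [calibrate_division_time()]
#' so that the time to first division under saturating nutrient equals
#' `doubling_time`.
#'
#' @param name Species identifier.
#' @param doubling_time Doubling time in minutes under saturating nutrient.
#' @param carbon_sources Character vector of usable nutrient names.
#' @param yield Energy units gained per nutrient unit consumed.
#' @param maintenance Energy units spent per timestep.
#' @param division_threshold Energy level that triggers division.
#' @param initial_energy Energy of newly seeded cells
#'   (`0 < initial_energy < division_threshold`).
#' @param mic Antibiotic concentration (field units) at or above which the
#'   kill rule applies; `Inf` marks a resistant strain.
#' @param growth_defect Fractional slowdown `d >= 0`; effective uptake is
#'   scaled by `1 / (1 + d)`, so the effective doubling time is roughly
#'   `(1 + d)` times `doubling_time`.
#' @param uptake_rate Maximum nutrient units consumed per timestep, or `NULL`
#'   to calibrate from `doubling_time`.
#' @return A `skinsim_species` list.
#' @examples
#' sp <- species_params("bsubtilis", doubling_time = 60,
#'                      carbon_sources = c("skin_carbon", "malate"),
#'                      yield = 0.8, mic = Inf)
#' calibrate_division_time(sp)
#' @export
species_params <- function(name, doubling_time, carbon_sources,
                           yield = 1, maintenance = 1,
                           division_threshold = 1000, initial_energy = 500,
                           mic = Inf, growth_defect = 0, uptake_rate = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (doubling_time <= 0) stop("`doubling_time` must be > 0", call. = FALSE)
  if (length(carbon_sources) == 0) {
    stop("`carbon_sources` must be non-empty", call. = FALSE)
  }
  if (yield <= 0) stop("`yield` must be > 0", call. = FALSE)
  if (maintenance < 0) stop("`maintenance` must be >= 0", call. = FALSE)
  if (!(division_threshold > initial_energy && initial_energy > 0)) {
    stop("need division_threshold > initial_energy > 0", call. = FALSE)
  }
  if (growth_defect < 0) stop("`growth_defect` must be >= 0", call. = FALSE)
  if (!is.null(uptake_rate) && uptake_rate <= 0) {
    stop("`uptake_rate` must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, doubling_time = doubling_time,
         carbon_sources = as.character(carbon_sources),
         uptake_rate = uptake_rate, yield = yield, maintenance = maintenance,
         division_threshold = division_threshold,
         initial_energy = initial_energy, mic = mic,
         growth_defect = growth_defect),
    class = "skinsim_species"
  )
}

#' Calibrate uptake so the emergent division interval matches the doubling time
#'
#' Under saturating nutrient an undefected agent gains
#' `yield * uptake_rate - maintenance` energy per step, so its first division
#' occurs after `ceiling((division_threshold - initial_energy) / gain)` steps.
#' This sets `uptake_rate` such that that step count equals
#' `round(doubling_time / minutes_per_timestep)` exactly.
#'
#' @param species A [species_params()] object.
#' @param clock A [model_clock()].
#' @return The species with `uptake_rate` set.
#' @export
calibrate_division_time <- function(species, clock = model_clock()) {
  stopifnot(inherits(species, "skinsim_species"))
  steps <- round(species$doubling_time / clock$minutes_per_timestep)
  if (steps < 1) {
    stop("doubling_time is below one timestep; cannot calibrate", call. = FALSE)
  }
  gain <- (species$division_threshold - species$initial_energy) / steps
  species$uptake_rate <- (species$maintenance + gain) / species$yield
  if (species$maintenance >= species$yield * species$uptake_rate) {
    stop("infeasible calibration: maintenance >= yield * uptake", call. = FALSE)
  }
  species
}

#' Closed-form steps to first division under saturating nutrient
#'
#' The independent energy-ledger prediction: an agent seeded at
#' `initial_energy` gaining `yield * uptake / (1 + defect) - maintenance` per
#' step reaches the division threshold after
#' `ceiling((division_threshold - initial_energy) / gain)` steps, or never
#' (`Inf`) when the net gain is non-positive.
#'
#' @inheritParams calibrate_division_time
#' @param growth_defect Optional defect overriding the species' own value.
#' @return Number of timesteps (possibly `Inf`).
#' @export
steps_to_divide <- function(species, clock = model_clock(),
                            growth_defect = NULL) {
  stopifnot(inherits(species, "skinsim_species"))
  if (is.null(species$uptake_rate)) species <- calibrate_division_time(species, clock)
  d <- if (is.null(growth_defect)) species$growth_defect else growth_defect
  gain <- species$yield * species$uptake_rate / (1 + d) - species$maintenance
  if (gain <= 0) return(Inf)
  ceiling((species$division_threshold - species$initial_energy) / gain - 1e-9)
}

#' Convert a list of species to a tibble
#'
#' @param species List of [species_params()] objects.
#' @return A tibble with one row per species; carbon sources are collapsed
#'   with `";"`.
#' @export
species_table <- function(species) {
  purrr::map_dfr(species, function(s) {
    tibble::tibble(
      name = s$name, doubling_time_min = s$doubling_time,
      carbon_sources = paste(s$carbon_sources, collapse = ";"),
      uptake_rate = s$uptake_rate %||% NA_real_, yield = s$yield,
      maintenance = s$maintenance,
      division_threshold = s$division_threshold,
      initial_energy = s$initial_energy, mic = s$mic,
      growth_defect = s$growth_defect
    )
  })
}

#' Read a species table from CSV
#'
#' Expected columns: `name`, `doubling_time_min`, `carbon_sources`
#' (`";"`-separated nutrient names) and optionally `uptake_rate`, `yield`,
#' `maintenance`, `division_threshold`, `initial_energy`, `mic`
#' (`Inf` = resistant), `growth_defect`.
#'
#' @param path CSV file path.
#' @return A list of [species_params()] objects.
#' @export
read_species_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("name", "doubling_time_min", "carbon_sources") %in% names(df)))
  get <- function(row, col, default) {
    if (col %in% names(df) && !is.na(row[[col]])) row[[col]] else default
  }
  purrr::map(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    species_params(
      name = row$name, doubling_time = row$doubling_time_min,
      carbon_sources = strsplit(row$carbon_sources, ";", fixed = TRUE)[[1]],
      uptake_rate = if ("uptake_rate" %in% names(df) && !is.na(row$uptake_rate)) row$uptake_rate else NULL,
      yield = get(row, "yield", 1), maintenance = get(row, "maintenance", 1),
      division_threshold = get(row, "division_threshold", 1000),
      initial_energy = get(row, "initial_energy", 500),
      mic = get(row, "mic", Inf), growth_defect = get(row, "growth_defect", 0)
    )
  })
}

#' Write a species table to CSV
#'
#' @param species List of [species_params()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species_csv <- function(species, path) {
  readr::write_csv(species_table(species), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
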