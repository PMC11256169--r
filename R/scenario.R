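#' Scenario configuration
#'
#' The full description of a simulation experiment: grid and clock, resident
#' species (seeded in equal numbers), the invader and its introduction, any
#' interventions, the horizon and replication.  The defaults are the
#' calibrated baseline: a 100 x 100 toroidal grid representing 1 cm2 of
#' skin, one-minute timesteps, three residents seeded with 500 cells each,
#' and a 500-cell invader introduced at timestep 4500 (day 3.125) with a
#' 9000-step horizon (6.25 days, 3.125 of them post-introduction).
#'
#' @param rows,cols Grid dimensions (toroidal patches).
#' @param area_cm2 Skin area represented by the whole grid.
#' @param carrying_capacity Maximum agents per patch.
#' @param minutes_per_timestep Clock resolution.
#' @param nutrients List of [nutrient()] definitions.
#' @param residents List of resident [species_params()].
#' @param n0 Initial cells per resident species (equal seeding).
#' @param invader Invader [species_params()] or `NULL` for none.
#' @param invader_n Invader inoculum size (cells).
#' @param invader_at_timestep Introduction timestep.
#' @param interventions Tibble of [intervention()] rows (may be `NULL`).
#' @param total_timesteps Simulation horizon in timesteps.
#' @param n_replicates Number of replicate simulations.
#' @param base_seed Replicate `r` runs with seed `base_seed + r`.
#' @param p_kill Per-step death probability when local antibiotic >= MIC.
#' @param antibiotic_half_life_min First-order antibiotic decay half-life.
#' @param forage_frac Agents move to a random neighbour patch when local
#'   usable nutrient falls below `forage_frac * uptake_rate`.
#' @param dose_map A [dose_map()].
#' @return A `skinsim_scenario` list.
#' @export
scenario_config <- function(rows = 100, cols = 100, area_cm2 = 1,
                            carrying_capacity = 40,
                            minutes_per_timestep = 1,
                            nutrients = default_nutrients(),
                            residents = default_residents(),
                            n0 = 500,
                            invader = default_invader(),
                            invader_n = 500,
                            invader_at_timestep = 4500,
                            interventions = NULL,
                            total_timesteps = 9000,
                            n_replicates = 3,
                            base_seed = 100,
                            p_kill = 0.1,
                            antibiotic_half_life_min = 720,
                            forage_frac = 0.1,
                            dose_map = skinsim::dose_map()) {
  config <- structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         area_cm2 = area_cm2,
         carrying_capacity = as.integer(carrying_capacity),
         clock = model_clock(minutes_per_timestep),
         nutrients = unname(nutrients), residents = unname(residents),
         n0 = as.integer(n0), invader = invader,
         invader_n = as.integer(invader_n),
         invader_at_timestep = as.integer(invader_at_timestep),
         interventions = interventions,
         total_timesteps = as.integer(total_timesteps),
         n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed),
         p_kill = p_kill,
         antibiotic_half_life_min = antibiotic_half_life_min,
         forage_frac = forage_frac,
         dose_map = dose_map),
    class = "skinsim_scenario"
  )
  validate_scenario(config)
  config
}

#' Validate a scenario configuration
#'
#' Checks the structural invariants of a scenario before any simulation is
#' run; errors describe the first violated constraint.
#'
#' @param config A `skinsim_scenario`.
#' @return `config`, invisibly.
#' @export
validate_scenario <- function(config) {
  if (!inherits(config, "skinsim_scenario")) {
    stop("`config` must be a skinsim_scenario", call. = FALSE)
  }
  with(config, {
    if (rows < 1 || cols < 1) stop("grid must be at least 1 x 1", call. = FALSE)
    if (carrying_capacity < 1) stop("carrying_capacity must be >= 1", call. = FALSE)
    if (length(residents) == 0) stop("resident species list is empty", call. = FALSE)
    if (n0 < 0) stop("n0 must be >= 0", call. = FALSE)
    if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
    if (total_timesteps < 1) stop("total_timesteps must be >= 1", call. = FALSE)
    if (!is.null(invader)) {
      if (invader_n < 0) stop("invader_n must be >= 0", call. = FALSE)
      if (total_timesteps <= invader_at_timestep) {
        stop("total_timesteps must exceed invader_at_timestep", call. = FALSE)
      }
    }
    if (n0 * length(residents) > rows * cols * carrying_capacity) {
      stop("configuration error: initial agents exceed grid capacity",
           call. = FALSE)
    }
  })
  for (nu in config$nutrients) stopifnot(inherits(nu, "skinsim_nutrient"))
  for (sp in config$residents) stopifnot(inherits(sp, "skinsim_species"))
  if (!is.null(config$interventions)) {
    stopifnot(all(config$interventions$at_timestep >= 0),
              all(config$interventions$magnitude >= 0))
  }
  invisible(config)
}

# every scheduled event, including the invader introduction, as one tibble
scenario_events <- function(config) {
  ev <- config$interventions
  if (!is.null(config$invader) && config$invader_n >= 0) {
    ev <- dplyr::bind_rows(
      intervention("introduce_invader", config$invader_at_timestep,
                   config$invader_n),
      ev
    )
  }
  if (is.null(ev) || nrow(ev) == 0) return(NULL)
  dplyr::arrange(ev, .data$at_timestep)
}

#' Named scenario presets
#'
#' * `"baseline"` -- the unperturbed community with the invader introduced at
#'   timestep 4500;
#' * `"antibiotic:D"` -- antibiotic at `D` mg/cm2 (0, 4, 8 or 10) applied at
#'   introduction;
#' * `"malate:A"` -- malate supplementation at `A` mol/cm2 (0, 37e-9, 3.7e-6
#'   or 0.37e-3) applied at introduction;
#' * `"growth_defect:d"` -- baseline with an invader growth defect `d`
#'   (0.1, 0.25, 0.5 or 1.0);
#' * `"lb_bolus"` -- a non-specific nutrient bolus applied at introduction.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [scenario_config()] (e.g. `base_seed`).
#' @return A `skinsim_scenario`.
#' @examples
#' preset("antibiotic:10")$interventions
#' @export
preset <- function(name, ...) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  arg <- if (length(parts) > 1) as.numeric(parts[2]) else NA_real_
  at <- 4500L
  config <- switch(kind,
    baseline = scenario_config(...),
    antibiotic = {
      if (is.na(arg)) stop("preset 'antibiotic:' needs a dose", call. = FALSE)
      scenario_config(interventions = intervention("antibiotic", at, arg), ...)
    },
    malate = {
      if (is.na(arg)) stop("preset 'malate:' needs a dose", call. = FALSE)
      scenario_config(
        interventions = intervention("carbon_supplement", at, arg,
                                     nutrient = "malate"), ...)
    },
    growth_defect = {
      if (is.na(arg)) stop("preset 'growth_defect:' needs a value", call. = FALSE)
      scenario_config(invader = default_invader(growth_defect = arg), ...)
    },
    lb_bolus = scenario_config(
      interventions = intervention("lb_bolus", at, 2e5), ...),
    stop("unknown preset: ", name, call. = FALSE)
  )
  attr(config, "preset") <- name
  config
}

#' Write a scenario to YAML
#'
#' @param config A `skinsim_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(config, path) {
  validate_scenario(config)
  ser_species <- function(s) {
    s <- unclass(s)
    s$mic <- if (is.infinite(s$mic)) ".inf" else s$mic
    s
  }
  obj <- list(
    grid = list(rows = config$rows, cols = config$cols,
                area_cm2 = config$area_cm2,
                carrying_capacity = config$carrying_capacity),
    clock = list(minutes_per_timestep = config$clock$minutes_per_timestep),
    nutrients = lapply(config$nutrients, unclass),
    residents = lapply(config$residents, ser_species),
    n0 = config$n0,
    invader = if (!is.null(config$invader)) ser_species(config$invader),
    invader_n = config$invader_n,
    invader_at_timestep = config$invader_at_timestep,
    interventions = if (!is.null(config$interventions)) {
      lapply(seq_len(nrow(config$interventions)), function(i) {
        iv <- as.list(config$interventions[i, ])
        if (is.na(iv$nutrient)) iv$nutrient <- NULL
        iv
      })
    },
    total_timesteps = config$total_timesteps,
    n_replicates = config$n_replicates,
    base_seed = config$base_seed,
    p_kill = config$p_kill,
    antibiotic_half_life_min = config$antibiotic_half_life_min,
    forage_frac = config$forage_frac,
    dose_map = unclass(config$dose_map)
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a scenario from YAML
#'
#' @param path A file written by [write_scenario_yaml()].
#' @return A `skinsim_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  de_species <- function(s) {
    if (identical(s$mic, ".inf")) s$mic <- Inf
    species_params(
      name = s$name, doubling_time = s$doubling_time,
      carbon_sources = unlist(s$carbon_sources),
      uptake_rate = s$uptake_rate, yield = s$yield,
      maintenance = s$maintenance,
      division_threshold = s$division_threshold,
      initial_energy = s$initial_energy, mic = s$mic,
      growth_defect = s$growth_defect
    )
  }
  ivs <- NULL
  if (!is.null(obj$interventions)) {
    ivs <- purrr::map_dfr(obj$interventions, function(iv) {
      intervention(iv$kind, iv$at_timestep, iv$magnitude,
                   nutrient = iv$nutrient %||% NA_character_)
    })
  }
  scenario_config(
    rows = obj$grid$rows, cols = obj$grid$cols,
    area_cm2 = obj$grid$area_cm2,
    carrying_capacity = obj$grid$carrying_capacity,
    minutes_per_timestep = obj$clock$minutes_per_timestep,
    nutrients = lapply(obj$nutrients, function(nu) do.call(nutrient, nu)),
    residents = lapply(obj$residents, de_species),
    n0 = obj$n0,
    invader = if (!is.null(obj$invader)) de_species(obj$invader),
    invader_n = obj$invader_n,
    invader_at_timestep = obj$invader_at_timestep,
    interventions = ivs,
    total_timesteps = obj$total_timesteps,
    n_replicates = obj$n_replicates,
    base_seed = obj$base_seed,
    p_kill = obj$p_kill,
    antibiotic_half_life_min = obj$antibiotic_half_life_min,
    forage_frac = obj$forage_frac,
    dose_map = do.call(dose_map, obj$dose_map)
  )
}

#' @export
print.skinsim_scenario <- function(x, ...) {
  cat("<skinsim_scenario> ", x$rows, "x", x$cols, " grid, ",
      x$total_timesteps, " steps, ", x$n_replicates, " replicate(s)\n",
      sep = "")
  cat("  residents:", paste(vapply(x$residents, `[[`, "", "name"),
                            collapse = ", "), "\n")
  if (!is.null(x$invader)) {
    cat("  invader: ", x$invader$name, " (n = ", x$invader_n,
        " at timestep ", x$invader_at_timestep, ")\n", sep = "")
  }
  ev <- x$interventions
  if (!is.null(ev) && nrow(ev) > 0) {
    cat("  interventions:",
        paste(ev$kind, "@", ev$at_timestep, "=", ev$magnitude,
              collapse = "; "), "\n")
  }
  invisible(x)
}
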