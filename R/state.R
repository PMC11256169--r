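#' Initialise a simulation state from a scenario configuration
#'
#' Seeds every resident species with `n0` agents at uniformly random patches
#' (respecting the per-patch carrying capacity), sets each nutrient field to
#' its initial amount, zeroes the antibiotic field and sets the clock to
#' timestep 0.  The invader species is registered (so its counts are tracked)
#' but not seeded; it enters later through [introduce_invader()].
#'
#' @param config A [scenario_config()].
#' @return A `skinsim_state` object.
#' @export
init_environment <- function(config) {
  validate_scenario(config)
  rows <- config$rows; cols <- config$cols
  npatch <- rows * cols

  species <- config$residents
  if (!is.null(config$invader)) species <- c(species, list(config$invader))
  species <- lapply(species, calibrate_if_needed, clock = config$clock)
  names(species) <- vapply(species, `[[`, "", "name")

  nutrient_names <- vapply(config$nutrients, `[[`, "", "name")
  fields <- lapply(config$nutrients, function(nu) {
    matrix(nu$initial_amount, rows, cols)
  })
  names(fields) <- nutrient_names

  species_cpp <- lapply(species, function(s) {
    idx <- match(s$carbon_sources, nutrient_names)
    if (anyNA(idx)) {
      stop("species '", s$name, "' uses unknown nutrient(s): ",
           paste(s$carbon_sources[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    list(uptake_rate = s$uptake_rate, yield = s$yield,
         maintenance = s$maintenance,
         division_threshold = s$division_threshold, mic = s$mic,
         growth_defect = s$growth_defect, source_idx = as.integer(idx - 1L))
  })

  n_res <- length(config$residents)
  total0 <- config$n0 * n_res
  if (total0 > npatch * config$carrying_capacity) {
    stop("configuration error: ", total0, " initial agents exceed grid ",
         "capacity ", npatch * config$carrying_capacity, call. = FALSE)
  }

  state <- structure(
    list(
      rows = rows, cols = cols, area_cm2 = config$area_cm2,
      carrying_capacity = config$carrying_capacity,
      clock = config$clock,
      nutrients = config$nutrients, nutrient_names = nutrient_names,
      fields = fields,
      antibiotic = matrix(0, rows, cols),
      species = species, species_names = names(species),
      species_cpp = species_cpp,
      agents = list(species = integer(), row = integer(), col = integer(),
                    energy = numeric()),
      timestep = 0L,
      control = list(
        p_kill = config$p_kill,
        ab_decay = 2^(-config$clock$minutes_per_timestep /
                        config$antibiotic_half_life_min),
        forage_frac = config$forage_frac
      ),
      dose_map = config$dose_map,
      counts_log = NULL
    ),
    class = "skinsim_state"
  )

  for (i in seq_len(n_res)) {
    state <- place_agents(state, species_index = i, n = config$n0,
                          energy = species[[i]]$initial_energy)
  }
  state$counts_log <- matrix(count_by_species(state), nrow = 1,
                             dimnames = list(NULL, state$species_names))
  state
}

calibrate_if_needed <- function(s, clock) {
  if (is.null(s$uptake_rate)) calibrate_division_time(s, clock) else s
}

# drop n agents of one species at uniformly random patches, re-drawing any
# placement that would exceed the per-patch carrying capacity
place_agents <- function(state, species_index, n, energy) {
  if (n == 0) return(state)
  npatch <- state$rows * state$cols
  occ <- tabulate(cell_index(state$agents$row, state$agents$col, state$rows),
                  nbins = npatch)
  cells <- integer(n)
  filled <- 0L
  while (filled < n) {
    draw <- sample.int(npatch, n - filled, replace = TRUE)
    for (cl in draw) {
      if (occ[cl] < state$carrying_capacity) {
        filled <- filled + 1L
        cells[filled] <- cl
        occ[cl] <- occ[cl] + 1L
      }
    }
  }
  rw <- ((cells - 1L) %% state$rows) + 1L
  cw <- ((cells - 1L) %/% state$rows) + 1L
  state$agents$species <- c(state$agents$species, rep.int(species_index, n))
  state$agents$row <- c(state$agents$row, rw)
  state$agents$col <- c(state$agents$col, cw)
  state$agents$energy <- c(state$agents$energy, rep.int(energy, n))
  state
}

cell_index <- function(row, col, rows) (col - 1L) * rows + row

count_by_species <- function(state) {
  tabulate(state$agents$species, nbins = length(state$species))
}

#' Advance the simulation
#'
#' Runs `n` full timesteps: nutrient replenishment and diffusion, antibiotic
#' decay, then every agent's update in a freshly shuffled order.  Per-species
#' population counts are appended to the state's count log after every step.
#'
#' @param state A `skinsim_state`.
#' @param n Number of timesteps.
#' @param watch_species Optional species name: stop early once its population
#'   reaches zero (used for survival-only runs).
#' @return The advanced state.
#' @export
advance <- function(state, n = 1, watch_species = NULL) {
  stopifnot(inherits(state, "skinsim_state"), n >= 0)
  if (n == 0) return(state)
  watch <- 0L
  if (!is.null(watch_species)) {
    watch <- match(watch_species, state$species_names)
    if (is.na(watch)) stop("unknown species: ", watch_species, call. = FALSE)
  }
  res <- cpp_run(
    state$fields, state$antibiotic,
    vapply(state$nutrients, `[[`, 0, "replenish_rate"),
    vapply(state$nutrients, `[[`, 0, "diffusivity"),
    unname(state$species_cpp),
    state$agents$species, state$agents$row, state$agents$col,
    state$agents$energy,
    state$carrying_capacity, state$control$p_kill, state$control$ab_decay,
    state$control$forage_frac, as.integer(n), as.integer(watch)
  )
  names(res$fields) <- state$nutrient_names
  state$fields <- res$fields
  state$antibiotic <- res$antibiotic
  state$agents <- list(species = res$species, row = res$row, col = res$col,
                       energy = res$energy)
  colnames(res$counts) <- state$species_names
  state$counts_log <- rbind(state$counts_log, res$counts)
  state$last_consumed <- setNames(colSums(res$consumed), state$nutrient_names)
  state$timestep <- state$timestep + res$steps_done
  state
}

#' Replenish and diffuse the nutrient fields
#'
#' Applies the field half of a timestep only: every patch gains its nutrient's
#' replenish rate, each field is smoothed (a patch keeps `1 - D` of its
#' content and spreads `D` equally over its eight toroidal neighbours, so
#' total mass is conserved), and the antibiotic field decays by its per-step
#' factor.  The clock does not advance and no agent acts.
#'
#' @param state A `skinsim_state`.
#' @return The updated state.
#' @export
replenish_and_diffuse <- function(state) {
  stopifnot(inherits(state, "skinsim_state"))
  res <- cpp_fields_update(
    state$fields, state$antibiotic,
    vapply(state$nutrients, `[[`, 0, "replenish_rate"),
    vapply(state$nutrients, `[[`, 0, "diffusivity"),
    state$control$ab_decay
  )
  names(res$fields) <- state$nutrient_names
  state$fields <- res$fields
  state$antibiotic <- res$antibiotic
  state
}

#' Run the update rule for a single agent
#'
#' Executes one agent's turn (consume, pay maintenance, starvation and
#' antibiotic death checks, division, forage movement) against the current
#' fields, without replenishment and without advancing the clock.  This is
#' the same compiled rule the full update loop applies to every agent.
#'
#' @param state A `skinsim_state`.
#' @param index Agent index (row into [agents()]).
#' @return A list with elements `state`, `survives` and `divided`.
#' @export
agent_step <- function(state, index) {
  stopifnot(inherits(state, "skinsim_state"),
            index >= 1, index <= length(state$agents$species))
  res <- cpp_agent_step(
    state$fields, state$antibiotic,
    vapply(state$nutrients, `[[`, 0, "replenish_rate"),
    vapply(state$nutrients, `[[`, 0, "diffusivity"),
    unname(state$species_cpp),
    state$agents$species, state$agents$row, state$agents$col,
    state$agents$energy,
    state$carrying_capacity, state$control$p_kill, state$control$ab_decay,
    state$control$forage_frac, as.integer(index)
  )
  names(res$fields) <- state$nutrient_names
  state$fields <- res$fields
  state$antibiotic <- res$antibiotic
  state$agents <- list(species = res$species, row = res$row, col = res$col,
                       energy = res$energy)
  list(state = state, survives = res$survives, divided = res$divided)
}

#' Current agents as a tibble
#'
#' @param state A `skinsim_state`.
#' @return A tibble with columns `species`, `row`, `col`, `energy`.
#' @export
agents <- function(state) {
  stopifnot(inherits(state, "skinsim_state"))
  tibble::tibble(
    species = state$species_names[state$agents$species],
    row = state$agents$row, col = state$agents$col,
    energy = state$agents$energy
  )
}

#' Current population counts as a tibble
#'
#' @param state A `skinsim_state`.
#' @return A tibble with columns `species`, `count`.
#' @export
population_counts <- function(state) {
  stopifnot(inherits(state, "skinsim_state"))
  tibble::tibble(species = state$species_names,
                 count = count_by_species(state))
}

#' @export
print.skinsim_state <- function(x, ...) {
  cat("<skinsim_state> ", x$rows, "x", x$cols, " grid, timestep ", x$timestep,
      " (day ", format(timestep_to_days(x$timestep, x$clock), digits = 4),
      ")\n", sep = "")
  cnt <- count_by_species(x)
  cat(paste0("  ", x$species_names, ": ", cnt, collapse = "\n"), "\n", sep = "")
  invisible(x)
}
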