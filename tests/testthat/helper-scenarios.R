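# Shared fixtures.  Small configurations for engine-level tests, and a cache
# so the expensive full-size runs used by several acceptance checks are
# computed once per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small community on a 20 x 20 grid with the default per-patch economy
small_config <- function(base_seed = 42, total_timesteps = 400, ...) {
  scenario_config(rows = 20, cols = 20, n0 = 50, invader_n = 50,
                  invader_at_timestep = 200,
                  total_timesteps = total_timesteps,
                  n_replicates = 2, base_seed = base_seed, ...)
}

# population tibble with the run metadata attributes removed, for comparing
# trajectories across configurations
strip_popts <- function(x) {
  x <- as.data.frame(x)
  attr(x, "config") <- NULL
  attr(x, "seeds") <- NULL
  attr(x, "truncated") <- NULL
  x
}

# single species able to divide exactly every `doubling_time` steps when food
# saturates
test_species <- function(doubling_time = 30, ...) {
  calibrate_division_time(
    species_params("tester", doubling_time = doubling_time,
                   carbon_sources = "food", ...)
  )
}

# a one-species, one-nutrient world used by the energy-ledger oracle tests
ledger_config <- function(rows = 1, cols = 1, replenish = 0, initial = 0,
                          species = test_species(), capacity = 1,
                          p_kill = 0.1) {
  scenario_config(
    rows = rows, cols = cols, carrying_capacity = capacity,
    nutrients = list(nutrient("food", diffusivity = 0,
                              replenish_rate = replenish,
                              initial_amount = initial)),
    residents = list(species), n0 = 1, invader = NULL,
    total_timesteps = 100, n_replicates = 1, p_kill = p_kill
  )
}

# independent single-agent energy-ledger oracle on a 1x1 world: returns the
# per-step agent count and energy of the founding lineage, modelling the same
# rules by explicit bookkeeping (saturating or drip feeding, capacity 1 so
# division is always deferred)
ledger_oracle <- function(species, replenish, initial, n_steps) {
  avail <- initial
  energy <- species$initial_energy
  u <- species$uptake_rate / (1 + species$growth_defect)
  alive <- TRUE
  out <- data.frame(step = seq_len(n_steps), count = NA_integer_,
                    energy = NA_real_)
  for (t in seq_len(n_steps)) {
    avail <- avail + replenish
    if (alive) {
      eat <- min(u, avail)
      avail <- avail - eat
      energy <- energy + species$yield * eat - species$maintenance
      if (energy <= 0) alive <- FALSE
    }
    out$count[t] <- as.integer(alive)
    out$energy[t] <- if (alive) energy else NA_real_
  }
  out
}

# --- cached full-size runs shared by the acceptance suite -------------------

baseline_full_run <- function() {
  fixture("baseline_full", {
    run_scenario(preset("baseline", n_replicates = 3, base_seed = 100))
  })
}

malate_max_run <- function() {
  fixture("malate_max", {
    run_scenario(preset("malate:0.37e-3", n_replicates = 3, base_seed = 100),
                 stop_after_invader_extinct = TRUE)
  })
}

antibiotic_max_run <- function() {
  fixture("antibiotic_max", {
    run_scenario(preset("antibiotic:10", n_replicates = 3, base_seed = 100))
  })
}

# invader survival sweep over growth defects: the pre-introduction community
# does not depend on the invader's defect, so each seed's first 4500 steps are
# simulated once and every defect branches from that snapshot
defect_sweep <- function(defects = c(0, 0.1, 0.25, 0.5, 1),
                         seeds = 1:10, base = 100) {
  fixture("defect_sweep", {
    purrr::map_dfr(seeds, function(s) {
      set.seed(base + s)
      cfg <- preset("baseline")
      pre <- advance(init_environment(cfg), cfg$invader_at_timestep)
      purrr::map_dfr(seq_along(defects), function(i) {
        st <- pre
        st$species_cpp[["bsubtilis"]]$growth_defect <- defects[i]
        set.seed((base + s) * 100 + i)
        st <- introduce_invader(st, "bsubtilis", cfg$invader_n)
        st <- advance(st, cfg$total_timesteps - st$timestep,
                      watch_species = "bsubtilis")
        cl <- st$counts_log[, "bsubtilis"]
        ext <- which(cl == 0 & seq_along(cl) - 1 > cfg$invader_at_timestep)
        surv <- if (length(ext) == 0) {
          (cfg$total_timesteps - cfg$invader_at_timestep) / 1440
        } else {
          (min(ext) - 1 - cfg$invader_at_timestep) / 1440
        }
        tibble::tibble(seed = s, defect = defects[i],
                       survival_days = surv, censored = length(ext) == 0)
      })
    })
  })
}
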