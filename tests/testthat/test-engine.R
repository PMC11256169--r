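test_that("seeding places equal resident populations and respects limits", {
  cfg <- scenario_config()
  set.seed(1)
  st <- init_environment(cfg)
  expect_equal(nrow(agents(st)), 1500)
  expect_equal(population_counts(st)$count, c(500, 500, 500, 0))
  expect_true(all(st$antibiotic == 0))
  expect_equal(st$timestep, 0L)

  # same config + seed twice gives identical placements
  set.seed(7); a <- agents(init_environment(cfg))
  set.seed(7); b <- agents(init_environment(cfg))
  expect_identical(a, b)

  # degenerate seeding: empty community, fields at initial values
  cfg0 <- scenario_config(n0 = 0, invader = NULL)
  st0 <- init_environment(cfg0)
  expect_equal(nrow(agents(st0)), 0)
  st0 <- advance(st0, 3)
  expect_equal(unname(st0$counts_log[4, ]), c(0, 0, 0))
  expect_equal(mean(st0$fields$sebum_lipid), 3 * 5.46, tolerance = 1e-12)

  # over-capacity seeding is a configuration error
  expect_error(
    scenario_config(rows = 2, cols = 2, carrying_capacity = 1, n0 = 10),
    "capacity")
})

test_that("diffusion conserves mass and has the stated local behaviour", {
  mk <- function(rows, cols, D, init = 0) {
    init_environment(scenario_config(
      rows = rows, cols = cols,
      nutrients = list(nutrient("food", diffusivity = D, replenish_rate = 0,
                                initial_amount = init)),
      residents = list(test_species()), n0 = 0, invader = NULL,
      total_timesteps = 10, n_replicates = 1))
  }
  # uniform field is invariant under diffusion at any D
  st <- mk(6, 6, D = 0.7, init = 3.25)
  st <- replenish_and_diffuse(st)
  expect_equal(st$fields$food, matrix(3.25, 6, 6))

  # single-patch spike with D = 1: all 8 neighbours get A/8, centre empties
  st <- mk(3, 3, D = 1)
  st$fields$food[2, 2] <- 8
  st <- replenish_and_diffuse(st)
  expect_equal(st$fields$food[2, 2], 0)
  expect_equal(sum(st$fields$food), 8, tolerance = 1e-12)
  expect_true(all(st$fields$food[-5] == 1))

  # random field: total mass conserved to 1e-9 relative
  st <- mk(12, 9, D = 0.33)
  set.seed(5)
  st$fields$food[] <- runif(12 * 9, 0, 50)
  before <- sum(st$fields$food)
  st <- replenish_and_diffuse(st)
  expect_equal(sum(st$fields$food), before, tolerance = 1e-9)

  # 1x1 torus: every neighbour is the patch itself, diffusion is a no-op
  st <- mk(1, 1, D = 0.9, init = 4)
  st <- replenish_and_diffuse(st)
  expect_equal(st$fields$food[1, 1], 4)
})

test_that("engine matches the single-agent energy-ledger oracle exactly", {
  sp <- test_species(doubling_time = 30)

  run_engine <- function(replenish, initial, n_steps) {
    cfg <- ledger_config(replenish = replenish, initial = initial, species = sp)
    set.seed(3)
    st <- init_environment(cfg)
    en <- cnt <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      st <- advance(st, 1)
      cnt[t] <- nrow(agents(st))
      en[t] <- if (cnt[t] > 0) agents(st)$energy else NA_real_
    }
    data.frame(step = seq_len(n_steps), count = cnt, energy = en)
  }

  # starvation: zero nutrient kills after ceiling(E0 / maintenance) steps
  got <- run_engine(0, 0, 510)
  ora <- ledger_oracle(sp, 0, 0, 510)
  expect_equal(got$count, ora$count)
  expect_equal(which(got$count == 0)[1],
               ceiling(sp$initial_energy / sp$maintenance))

  # drip feeding below subsistence: death delayed exactly as the ledger says
  got <- run_engine(0.4 * sp$maintenance, 10, 900)
  ora <- ledger_oracle(sp, 0.4 * sp$maintenance, 10, 900)
  expect_equal(got$count, ora$count)
  expect_equal(got$energy, ora$energy)

  # saturating feeding: energy trajectories identical step by step
  got <- run_engine(0, 1e7, 200)
  ora <- ledger_oracle(sp, 0, 1e7, 200)
  expect_equal(got$energy, ora$energy)
})

test_that("division occurs on schedule and respects carrying capacity", {
  sp <- test_species(doubling_time = 30)
  cfg <- scenario_config(
    rows = 5, cols = 5, carrying_capacity = 40,
    nutrients = list(nutrient("food", diffusivity = 0, replenish_rate = 0,
                              initial_amount = 1e7)),
    residents = list(sp), n0 = 1, invader = NULL,
    total_timesteps = 100, n_replicates = 1)
  set.seed(11)
  st <- init_environment(cfg)
  st <- advance(st, 65)
  cl <- st$counts_log[, 1]
  expect_equal(unname(cl[30]), 1)    # step 29: not yet divided
  expect_equal(unname(cl[31]), 2)    # first division exactly at step 30
  expect_equal(unname(cl[61]), 4)    # both offspring divide at step 60
  expect_true(all(is.finite(agents(st)$energy)))

  # saturated world: population is capped by rows * cols * capacity
  cfg2 <- scenario_config(
    rows = 4, cols = 4, carrying_capacity = 8,
    nutrients = list(nutrient("food", diffusivity = 0.2, replenish_rate = 1e5)),
    residents = list(sp), n0 = 4, invader = NULL,
    total_timesteps = 100, n_replicates = 1)
  set.seed(2)
  st2 <- advance(init_environment(cfg2), 600)
  expect_lte(max(st2$counts_log[, 1]), 4 * 4 * 8)
  expect_gt(max(st2$counts_log[, 1]), 4 * 4 * 8 * 0.8)  # actually fills up
  occ <- dplyr::count(agents(st2), row, col)
  expect_lte(max(occ$n), 8)   # no patch ever over capacity
})

test_that("per-patch occupancy never exceeds capacity in a growing community", {
  cfg <- small_config(invader = NULL)
  set.seed(9)
  st <- init_environment(cfg)
  for (i in 1:6) {
    st <- advance(st, 50)
    occ <- dplyr::count(agents(st), row, col)
    expect_lte(max(occ$n), cfg$carrying_capacity)
  }
})

test_that("one timestep's nutrient books balance: supply in, consumption out", {
  cfg <- small_config(invader = NULL)
  set.seed(4)
  st <- advance(init_environment(cfg), 100)  # mid-run, all fields grazed
  before <- vapply(st$fields, sum, 0)
  st <- advance(st, 1)
  after <- vapply(st$fields, sum, 0)
  supply <- vapply(st$nutrients, `[[`, 0, "replenish_rate") * st$rows * st$cols
  expect_equal(after, before + supply - st$last_consumed, tolerance = 1e-9)
})

test_that("identical seed and configuration give bit-identical trajectories", {
  cfg <- small_config()
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # and the exported CSV is byte-identical
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(a, f1); write_population_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # different seeds diverge
  c2 <- run_scenario(small_config(base_seed = 43))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("agent_step applies starvation, kill and division rules", {
  sp <- test_species(doubling_time = 30)
  base_cfg <- function(p_kill, mic = 1, init = 0) {
    spx <- sp; spx$mic <- mic
    ledger_config(replenish = 0, initial = init, species = spx,
                  capacity = 4, p_kill = p_kill)
  }

  # starvation death on the agent's own turn once energy hits zero
  cfg <- base_cfg(p_kill = 1)
  set.seed(1); st <- init_environment(cfg)
  st$agents$energy <- 0.5
  res <- agent_step(st, 1)
  expect_false(res$survives)
  expect_equal(nrow(agents(res$state)), 0)

  # antibiotic at/above MIC with p_kill = 1 kills a sensitive agent ...
  set.seed(1); st <- init_environment(cfg)
  st$antibiotic[] <- 1
  res <- agent_step(st, 1)
  expect_false(res$survives)

  # ... but a resistant agent (mic = Inf) is untouched at any concentration
  cfg_r <- base_cfg(p_kill = 1, mic = Inf)
  set.seed(1); st <- init_environment(cfg_r)
  st$antibiotic[] <- 1e12
  res <- agent_step(st, 1)
  expect_true(res$survives)

  # an agent at the division threshold divides; energy splits exactly in half
  cfg_d <- base_cfg(p_kill = 0)
  set.seed(1); st <- init_environment(cfg_d)
  st$agents$energy <- sp$division_threshold + sp$maintenance
  res <- agent_step(st, 1)
  expect_true(res$divided)
  en <- agents(res$state)$energy
  expect_equal(length(en), 2)
  expect_equal(en[1], en[2])
  expect_equal(sum(en), sp$division_threshold)
})
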