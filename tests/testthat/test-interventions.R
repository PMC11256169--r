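test_that("antibiotic dose maps linearly onto MIC multiples", {
  expect_identical(dose_to_mic_multiple(10), 1000)
  expect_identical(dose_to_mic_multiple(0), 0)
  expect_identical(dose_to_mic_multiple(4), 400)
  expect_identical(dose_to_mic_multiple(8), 800)
  expect_error(dose_to_mic_multiple(-1), "dose")
  # the anchor point is configurable
  dm <- dose_map(mg_per_cm2_per_1000mic = 5)
  expect_identical(dose_to_mic_multiple(5, dm), 1000)
})

test_that("antibiotic application sets a uniform super-MIC field", {
  cfg <- small_config()
  set.seed(1); st <- init_environment(cfg)
  st <- apply_antibiotic(st, 10)
  mics <- vapply(default_residents(), `[[`, 0, "mic")
  expect_true(all(st$antibiotic >= max(mics)))        # every patch >= MIC
  expect_lt(diff(range(st$antibiotic)), 1e-12)        # uniform
  expect_equal(st$antibiotic[1, 1], 1000 * st$dose_map$mic_reference)
  # dose 0 leaves the field at zero
  set.seed(1); st0 <- apply_antibiotic(init_environment(cfg), 0)
  expect_true(all(st0$antibiotic == 0))
})

test_that("antibiotic decays with the configured half-life", {
  cfg <- small_config(invader = NULL, antibiotic_half_life_min = 720)
  set.seed(1)
  st <- apply_antibiotic(init_environment(cfg), 10)
  st <- advance(st, 720)
  expect_equal(st$antibiotic[3, 3], 500, tolerance = 1e-9)
})

test_that("carbon supplement arithmetic distributes the dose over patches", {
  cfg <- small_config()
  set.seed(1); st <- init_environment(cfg)
  dm <- st$dose_map
  st2 <- apply_carbon_supplement(st, 0.37e-3)
  gain <- st2$fields$malate - st$fields$malate
  expect_equal(gain[1, 1],
               0.37e-3 * st$area_cm2 * dm$mol_to_field_units / (20 * 20))
  expect_lt(diff(range(gain)), 1e-12)
  # zero dose is a no-op
  expect_equal(apply_carbon_supplement(st, 0)$fields$malate,
               st$fields$malate)
  expect_error(apply_carbon_supplement(st, 1e-6, "nope"), "unknown nutrient")
})

test_that("residents draw no energy from the invader-exclusive malate", {
  # a malate-flooded world with no shared food: residents starve on schedule
  # exactly as if no malate were present, because they cannot consume it
  res <- lapply(default_residents(), function(s) { s$carbon_sources; s })
  cfg <- scenario_config(
    rows = 5, cols = 5,
    nutrients = list(nutrient("malate", initial_amount = 1e6),
                     nutrient("sebum_lipid"), nutrient("sweat_peptide"),
                     nutrient("amino_acid"), nutrient("skin_carbon")),
    residents = res, n0 = 5, invader = NULL,
    total_timesteps = 1200, n_replicates = 1)
  set.seed(6)
  st <- advance(init_environment(cfg), 1100)
  expect_equal(sum(st$counts_log[nrow(st$counts_log), ]), 0)
  # malate only consumed by nobody: field mass intact
  expect_equal(sum(st$fields$malate), 25 * 1e6, tolerance = 1e-9)
})

test_that("LB bolus adds the stated mass to the shared pool for everyone", {
  cfg <- small_config()
  set.seed(1); st <- init_environment(cfg)
  st2 <- apply_lb_bolus(st, 12345)
  expect_equal(sum(st2$fields$skin_carbon) - sum(st$fields$skin_carbon),
               12345, tolerance = 1e-9)
  expect_equal(apply_lb_bolus(st, 0)$fields$skin_carbon,
               st$fields$skin_carbon)
  # every species lists a source able to reach it or its own niche; the shared
  # pool itself is usable by all four default species
  sp <- c(default_residents(), list(default_invader()))
  shared_users <- vapply(sp, function(s) "skin_carbon" %in% s$carbon_sources,
                         TRUE)
  expect_true(shared_users[[3]] && shared_users[[4]])
})

test_that("invader introduction jumps the count at the introduction step", {
  cfg <- small_config()
  set.seed(1)
  st <- advance(init_environment(cfg), 10)
  expect_error(introduce_invader(st, "bsubtilis", 50, at_timestep = 99),
               "scheduled")
  expect_error(introduce_invader(st, "nobody", 50), "unknown species")
  st <- introduce_invader(st, "bsubtilis", 50)
  expect_equal(population_counts(st)$count[4], 50)
  # logged count at the introduction timestep reflects the jump
  expect_equal(unname(st$counts_log[11, "bsubtilis"]), 50)
  # introductions are additive
  st <- introduce_invader(st, "bsubtilis", 25)
  expect_equal(population_counts(st)$count[4], 75)
  # n = 0 changes nothing
  before <- agents(st)
  st <- introduce_invader(st, "bsubtilis", 0)
  expect_identical(agents(st), before)
})

test_that("full run: dose 0 equals baseline; dose 10 suppresses residents only", {
  cfg0 <- small_config()
  cfgA <- small_config(interventions = intervention("antibiotic", 200, 0))
  a <- run_scenario(cfg0); b <- run_scenario(cfgA)
  expect_identical(strip_popts(a), strip_popts(b))

  cfgB <- small_config(interventions = intervention("antibiotic", 200, 10),
                       total_timesteps = 300)
  ts <- run_scenario(cfgB)
  res_end <- subset(ts, timestep == 300 & species != "bsubtilis" &
                      replicate == 1)
  res_pre <- subset(ts, timestep == 199 & species != "bsubtilis" &
                      replicate == 1)
  expect_true(all(res_end$count < res_pre$count))  # residents collapse
  inv <- subset(ts, species == "bsubtilis" & replicate == 1)
  expect_equal(inv$count[inv$timestep == 200], 50)  # resistant invader intact
  expect_gt(inv$count[inv$timestep == 220], 0)
})
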