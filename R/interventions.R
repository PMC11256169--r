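#' Dose conversion map
#'
#' Anchors the physical dose units of interventions to the model's field
#' units.  The antibiotic mapping is linear and pinned at one point: a dose of
#' `mg_per_cm2_per_1000mic` mg/cm2 equals 1000 times the resident MIC.
#' `mol_to_field_units` converts a carbon dose in moles into nutrient field
#' units; its default is calibrated so the highest malate dose studied
#' (0.37 mmol/cm2) is a community-scale nutrient pulse (see the vignette).
#'
#' @param mic_reference Resident-species MIC expressed in antibiotic field
#'   units (the default species table uses 1).
#' @param mg_per_cm2_per_1000mic Antibiotic dose in mg/cm2 corresponding to
#'   1000x MIC.
#' @param mol_to_field_units Field units per mole of supplemented carbon.
#' @return A `skinsim_dose_map` list.
#' @export
dose_map <- function(mic_reference = 1, mg_per_cm2_per_1000mic = 10,
                     mol_to_field_units = 5e10) {
  stopifnot(mic_reference > 0, mg_per_cm2_per_1000mic > 0,
            mol_to_field_units > 0)
  structure(
    list(mic_reference = mic_reference,
         mg_per_cm2_per_1000mic = mg_per_cm2_per_1000mic,
         mol_to_field_units = mol_to_field_units),
    class = "skinsim_dose_map"
  )
}

#' Convert an antibiotic dose to a MIC multiple
#'
#' Linear map: `dose * 1000 / mg_per_cm2_per_1000mic`, so the default 10
#' mg/cm2 corresponds to exactly 1000x the resident MIC.
#'
#' @param dose_mg_per_cm2 Antibiotic dose in mg/cm2 (>= 0).
#' @param dosemap A [dose_map()].
#' @return The dose as a multiple of the resident MIC.
#' @examples
#' dose_to_mic_multiple(10)  # 1000
#' dose_to_mic_multiple(4)   # 400
#' @export
dose_to_mic_multiple <- function(dose_mg_per_cm2, dosemap = dose_map()) {
  if (any(dose_mg_per_cm2 < 0)) stop("dose must be >= 0", call. = FALSE)
  dose_mg_per_cm2 * 1000 / dosemap$mg_per_cm2_per_1000mic
}

#' Introduce the invader population
#'
#' Adds `n_cells` agents of a registered species at uniformly random patches,
#' each carrying the species' initial energy.
#'
#' @param state A `skinsim_state`.
#' @param species Name of a species registered in the state.
#' @param n_cells Number of cells to add.
#' @param at_timestep Introduction timestep; must equal the state's current
#'   timestep.
#' @return The updated state.
#' @export
introduce_invader <- function(state, species, n_cells,
                              at_timestep = state$timestep) {
  stopifnot(inherits(state, "skinsim_state"), n_cells >= 0)
  idx <- match(species, state$species_names)
  if (is.na(idx)) stop("unknown species: ", species, call. = FALSE)
  if (at_timestep != state$timestep) {
    stop("introduction scheduled for timestep ", at_timestep,
         " but state is at ", state$timestep, call. = FALSE)
  }
  state <- place_agents(state, idx, n_cells,
                        energy = state$species[[idx]]$initial_energy)
  refresh_count_row(state)
}

#' Apply a uniform antibiotic dose
#'
#' Sets the antibiotic field on every patch to
#' `dose_to_mic_multiple(dose) * mic_reference`; the field subsequently
#' decays with the scenario's antibiotic half-life.
#'
#' @param state A `skinsim_state`.
#' @param dose_mg_per_cm2 Dose in mg/cm2.
#' @param dosemap A [dose_map()]; defaults to the one carried by the state.
#' @return The updated state.
#' @export
apply_antibiotic <- function(state, dose_mg_per_cm2,
                             dosemap = state$dose_map) {
  stopifnot(inherits(state, "skinsim_state"))
  conc <- dose_to_mic_multiple(dose_mg_per_cm2, dosemap) * dosemap$mic_reference
  state$antibiotic[] <- conc
  state
}

#' Supplement a carbon source
#'
#' Distributes `amount_mol_per_cm2 * area_cm2 * mol_to_field_units` nutrient
#' units equally across all patches of the named field.
#'
#' @param state A `skinsim_state`.
#' @param amount_mol_per_cm2 Dose in mol/cm2 (>= 0).
#' @param nutrient_name Target nutrient field (default `"malate"`, the
#'   invader-exclusive source).
#' @param dosemap A [dose_map()]; defaults to the one carried by the state.
#' @return The updated state.
#' @export
apply_carbon_supplement <- function(state, amount_mol_per_cm2,
                                    nutrient_name = "malate",
                                    dosemap = state$dose_map) {
  stopifnot(inherits(state, "skinsim_state"), amount_mol_per_cm2 >= 0)
  if (!nutrient_name %in% state$nutrient_names) {
    stop("unknown nutrient: ", nutrient_name, call. = FALSE)
  }
  total <- amount_mol_per_cm2 * state$area_cm2 * dosemap$mol_to_field_units
  per_patch <- total / (state$rows * state$cols)
  state$fields[[nutrient_name]] <- state$fields[[nutrient_name]] + per_patch
  state
}

#' Apply a non-specific nutrient bolus
#'
#' Adds `amount` nutrient units (total, spread uniformly) to the shared
#' `skin_carbon` field, which every species can consume -- the model analogue
#' of applying LB medium to the skin.
#'
#' @param state A `skinsim_state`.
#' @param amount Total nutrient units added (>= 0).
#' @return The updated state.
#' @export
apply_lb_bolus <- function(state, amount) {
  stopifnot(inherits(state, "skinsim_state"), amount >= 0)
  per_patch <- amount / (state$rows * state$cols)
  state$fields[["skin_carbon"]] <- state$fields[["skin_carbon"]] + per_patch
  state
}

# after an intervention at the current timestep, the logged counts for this
# timestep must reflect the post-intervention state
refresh_count_row <- function(state) {
  state$counts_log[nrow(state$counts_log), ] <- count_by_species(state)
  state
}

#' Declare an intervention for a scenario
#'
#' @param kind One of `"introduce_invader"`, `"antibiotic"`,
#'   `"carbon_supplement"`, `"lb_bolus"`.
#' @param at_timestep Application timestep (>= 0).
#' @param magnitude Dose in the intervention's natural unit: cells for the
#'   invader, mg/cm2 for the antibiotic, mol/cm2 for a carbon supplement,
#'   total field units for an LB bolus.
#' @param nutrient Target nutrient for `carbon_supplement`.
#' @return A one-row tibble.
#' @export
intervention <- function(kind, at_timestep, magnitude, nutrient = NA_character_) {
  kind <- match.arg(kind, c("introduce_invader", "antibiotic",
                            "carbon_supplement", "lb_bolus"))
  stopifnot(at_timestep >= 0, magnitude >= 0)
  tibble::tibble(kind = kind, at_timestep = as.integer(at_timestep),
                 magnitude = as.numeric(magnitude), nutrient = nutrient)
}

apply_one_intervention <- function(state, iv, config) {
  switch(iv$kind,
    introduce_invader = introduce_invader(state, config$invader$name,
                                          iv$magnitude, iv$at_timestep),
    antibiotic = refresh_count_row(
      apply_antibiotic(state, iv$magnitude, config$dose_map)),
    carbon_supplement = refresh_count_row(apply_carbon_supplement(
      state, iv$magnitude,
      nutrient_name = if (is.na(iv$nutrient)) "malate" else iv$nutrient,
      dosemap = config$dose_map)),
    lb_bolus = refresh_count_row(apply_lb_bolus(state, iv$magnitude)),
    stop("unknown intervention kind: ", iv$kind, call. = FALSE)
  )
}
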