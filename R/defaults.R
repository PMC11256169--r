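#' Default nutrient fields of the skin environment
#'
#' Five fields represent the niche structure of the modelled skin surface:
#'
#' * `sebum_lipid` -- sebaceous lipids, consumed by the Corynebacteria-like
#'   resident;
#' * `sweat_peptide` -- sweat-derived peptides, consumed by the
#'   Staphylococci-like resident;
#' * `amino_acid` -- sweat free amino acids, consumed by the
#'   Acinetobacter-like resident;
#' * `skin_carbon` -- a generic shared carbon pool open to every species (the
#'   Acinetobacter-like resident and the invader both draw on it, so they
#'   compete directly; a non-specific nutrient bolus such as LB is added
#'   here);
#' * `malate` -- exclusive carbon source of the *B. subtilis*-like invader;
#'   not secreted by the skin, only present when supplemented.
#'
#' Replenish rates are per patch per timestep on the default 100 x 100 grid
#' and are the calibrated values that place the resident community at roughly
#' 84/15/1 percent relative abundance (see the package vignette and
#' `scripts/calibrate.R` in the source repository).
#'
#' @return Named list of [nutrient()] objects.
#' @export
default_nutrients <- function() {
  list(
    sebum_lipid   = nutrient("sebum_lipid",   diffusivity = 0.2, replenish_rate = 5.46),
    sweat_peptide = nutrient("sweat_peptide", diffusivity = 0.2, replenish_rate = 0.975),
    amino_acid    = nutrient("amino_acid",    diffusivity = 0.2, replenish_rate = 0.105),
    skin_carbon   = nutrient("skin_carbon",   diffusivity = 0.2, replenish_rate = 0.045),
    malate        = nutrient("malate",        diffusivity = 0.2, replenish_rate = 0)
  )
}

#' Default resident species of the skin community
#'
#' Three residents stand in for the dominant genera of dry/sebaceous human
#' skin: a Corynebacteria-like, a Staphylococci-like and an
#' Acinetobacter-like population.  Each occupies its own nutrient niche (the
#' Acinetobacter-like species additionally draws on the shared carbon pool),
#' which is what keeps the community composition stable: on a single shared
#' resource the model's scramble competition collapses to competitive
#' exclusion.  All residents share the same energy economics; their relative
#' abundances are therefore set by the nutrient supply rates.
#'
#' Uptake rates are calibrated with [calibrate_division_time()] so the time
#' to first division under saturating nutrient equals the stated doubling
#' time.
#'
#' @return List of calibrated [species_params()] objects.
#' @export
default_residents <- function() {
  lapply(list(
    species_params("corynebacteria", doubling_time = 60,
                   carbon_sources = "sebum_lipid", mic = 1),
    species_params("staphylococci", doubling_time = 45,
                   carbon_sources = "sweat_peptide", mic = 1),
    species_params("acinetobacter", doubling_time = 40,
                   carbon_sources = c("amino_acid", "skin_carbon"),
                   maintenance = 2, mic = 1)
  ), calibrate_division_time)
}

#' Default engineered invader
#'
#' A *B. subtilis*-like strain: antibiotic-resistant (`mic = Inf`, the
#' plasmid carries the resistance marker), able to use the shared skin carbon
#' pool and, exclusively among all species, malate.  Its maintenance cost is
#' above the residents' (it is not adapted to the skin environment and
#' carries a heterologous construct), so its energy budget is negative at any
#' food level the resident community leaves available -- which is what
#' drives its rapid competitive exclusion in the unperturbed community, while
#' still allowing net growth on abundant malate and a positive budget when
#' the shared pool is freed by an antibiotic.
#'
#' @param growth_defect Fractional growth defect of the engineered strain.
#' @return A calibrated [species_params()] object.
#' @export
default_invader <- function(growth_defect = 0) {
  calibrate_division_time(
    species_params("bsubtilis", doubling_time = 60,
                   carbon_sources = c("skin_carbon", "malate"),
                   maintenance = 1.6, initial_energy = 770, mic = Inf,
                   growth_defect = growth_defect)
  )
}
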