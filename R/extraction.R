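#' Solute physicochemical properties
#'
#' Container for the constants driving oil/water partitioning: aqueous
#' solubility, octanol-water logP, solubilities in common organic solvents,
#' and identification metadata.
#'
#' @param name analyte label.
#' @param water_solubility_mg_L aqueous solubility, mg/L, positive.
#' @param logP octanol-water log10 partition coefficient (may be NA if a
#'   partition coefficient will be supplied directly).
#' @param solubility_in named numeric vector, mg/mL per solvent.
#' @param molar_mass g/mol.
#' @param pKa acid dissociation constant.
#' @param melting_point_C degrees Celsius.
#' @return object of class `solute_properties`.
#' @export
solute_properties <- function(name, water_solubility_mg_L, logP = NA_real_,
                              solubility_in = numeric(), molar_mass = NA_real_,
                              pKa = NA_real_, melting_point_C = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(water_solubility_mg_L), water_solubility_mg_L > 0)
  if (length(solubility_in) && any(solubility_in <= 0)) {
    stop("all solubilities must be positive", call. = FALSE)
  }
  structure(list(name = name,
                 water_solubility_mg_L = water_solubility_mg_L,
                 logP = logP, solubility_in = solubility_in,
                 molar_mass = molar_mass, pKa = pKa,
                 melting_point_C = melting_point_C),
            class = "solute_properties")
}

#' Bundled cannabinoid property records
#'
#' THC: aqueous solubility 0.0028 mg/mL (2.8 mg/L); logP 6.97 is the standard
#' literature value for delta-9-THC. CBD: water solubility 12.6 mg/L, logP
#' 6.3, pKa 9.1, melting point 67 C, molar mass 314 g/mol, with solubilities
#' of roughly 35, 30, 60 and 50 mg/mL in ethanol, methanol, DMSO and
#' dimethylformamide.
#'
#' @param analyte `"THC"` or `"CBD"`.
#' @return a [solute_properties()] object.
#' @export
cannabinoid_properties <- function(analyte = c("THC", "CBD")) {
  analyte <- match.arg(analyte)
  if (analyte == "THC") {
    solute_properties("delta9-THC", water_solubility_mg_L = 2.8,
                      logP = 6.97, molar_mass = 314.5)
  } else {
    solute_properties("CBD", water_solubility_mg_L = 12.6, logP = 6.3,
                      solubility_in = c(ethanol = 35, methanol = 30,
                                        DMSO = 60, dimethylformamide = 50),
                      molar_mass = 314, pKa = 9.1, melting_point_C = 67)
  }
}

#' Oil/water partition coefficient from logP
#'
#' `K = similarity * 10^logP`, where `similarity` (default 1) rescales the
#' octanol-water coefficient to the vegetable-oil/water pair. Cannabinoids are
#' strongly lipophilic (CBD logP 6.3), so K is of order 10^6 and the oil phase
#' dominates at equilibrium.
#'
#' @param props a [solute_properties()] with a finite `logP`.
#' @param similarity oil/octanol similarity factor, positive, default 1.
#' @return dimensionless partition coefficient (oil over water).
#' @examples
#' partition_coefficient(cannabinoid_properties("CBD"))  # ~2e6
#' @export
partition_coefficient <- function(props, similarity = 1) {
  stopifnot(inherits(props, "solute_properties"),
            is.numeric(similarity), similarity > 0)
  if (!is.finite(props$logP)) {
    stop("`logP` is missing for ", props$name,
         "; supply a partition coefficient K directly", call. = FALSE)
  }
  similarity * 10^props$logP
}

#' Roasting/washing extraction experiment descriptor
#'
#' Protocol settings for the selective-extraction simulation: seeds roasted in
#' edible oil at 50 C for 30 min, then washed with water at four times the
#' seed mass per cycle. Oil fractions of 10-40% of seed mass are the tested
#' range; outside it a warning is issued. Temperature is recorded metadata
#' only (the protocol fixes 50 C).
#'
#' @param seed_mass_g seed mass, g (default 5).
#' @param oil_type one of `"canola"`, `"palm"`, `"soybean"`, `"HSDM"`.
#' @param oil_fraction oil mass as a fraction of seed mass (default 0.40).
#' @param temperature_C roasting temperature (default 50).
#' @param duration_min roasting duration (default 30).
#' @param wash_water_ratio wash water mass per cycle, as a multiple of seed
#'   mass (default 4; 1 g water = 1 mL).
#' @param wash_cycles number of wash cycles (default 4).
#' @param reuse_water if TRUE the same wash water is reused across cycles
#'   (solute accumulates towards the solubility cap); default FALSE, fresh
#'   water per cycle.
#' @param k_per_min first-order extraction rate constant (default 0.2).
#' @param oil_absorption_g_per_g oil retained by the seeds, g oil per g seed
#'   (default 0.025, so 5-25% of input oil stays absorbed across the 10-40%
#'   oil grid).
#' @param oil_phase_split fraction of roast-extracted THC that leaves with the
#'   recovered free oil (default 0.10; separated oils showed no cannabinoid
#'   peaks, so most extracted THC is routed to the absorbed-oil/surface pool).
#' @param wash_efficiency per-cycle fraction of the surface pool contacted by
#'   the wash water (default 0.8), before the solubility cap applies.
#' @return object of class `extraction_experiment`.
#' @export
extraction_experiment <- function(seed_mass_g = 5,
                                  oil_type = c("soybean", "canola", "palm",
                                               "HSDM"),
                                  oil_fraction = 0.40,
                                  temperature_C = 50,
                                  duration_min = 30,
                                  wash_water_ratio = 4,
                                  wash_cycles = 4,
                                  reuse_water = FALSE,
                                  k_per_min = 0.2,
                                  oil_absorption_g_per_g = 0.025,
                                  oil_phase_split = 0.10,
                                  wash_efficiency = 0.8) {
  oil_type <- match.arg(oil_type)
  stopifnot(seed_mass_g > 0, oil_fraction > 0, oil_fraction <= 1,
            duration_min >= 0, wash_water_ratio > 0, wash_cycles >= 0,
            k_per_min >= 0, oil_absorption_g_per_g >= 0,
            oil_phase_split >= 0, oil_phase_split <= 1,
            wash_efficiency >= 0, wash_efficiency <= 1)
  if (oil_fraction < 0.10 || oil_fraction > 0.40) {
    warning("oil_fraction outside the tested 10-40% range", call. = FALSE)
  }
  structure(list(seed_mass_g = seed_mass_g, oil_type = oil_type,
                 oil_fraction = oil_fraction, temperature_C = temperature_C,
                 duration_min = duration_min,
                 wash_water_ratio = wash_water_ratio,
                 wash_cycles = wash_cycles, reuse_water = reuse_water,
                 k_per_min = k_per_min,
                 oil_absorption_g_per_g = oil_absorption_g_per_g,
                 oil_phase_split = oil_phase_split,
                 wash_efficiency = wash_efficiency),
            class = "extraction_experiment")
}

#' Husk/kernel THC mass pools of a seed lot
#'
#' Converts the archetype (volume fractions, density ratio, concentrations)
#' into THC masses: the husk mass fraction is
#' `f_H rho_ratio / (f_H rho_ratio + 1 - f_H)` and each pool's THC mass (mg)
#' is its mass (kg) times its concentration (mg/kg). Only the husk pool is
#' accessible to roasting extraction; the kernel pool is shielded inside the
#' seed.
#'
#' @param seed_mass_g total seed mass, g.
#' @param seed list with `f_H`, `rho_ratio`, `C_H`, `C_C`
#'   (default [hemp_seed_archetype()]).
#' @return list with `husk_mass_g`, `kernel_mass_g`, `husk_thc_mg`,
#'   `kernel_thc_mg`, `total_thc_mg`.
#' @export
seed_thc_pools <- function(seed_mass_g, seed = hemp_seed_archetype()) {
  stopifnot(seed_mass_g > 0)
  w_H <- seed$f_H * seed$rho_ratio /
    (seed$f_H * seed$rho_ratio + (1 - seed$f_H))
  husk_mass_g <- seed_mass_g * w_H
  kernel_mass_g <- seed_mass_g - husk_mass_g
  husk_thc_mg <- husk_mass_g / 1000 * seed$C_H
  kernel_thc_mg <- kernel_mass_g / 1000 * seed$C_C
  list(husk_mass_g = husk_mass_g, kernel_mass_g = kernel_mass_g,
       husk_thc_mg = husk_thc_mg, kernel_thc_mg = kernel_thc_mg,
       total_thc_mg = husk_thc_mg + kernel_thc_mg)
}

new_partition_result <- function(exp, pools, thc_in_oil, thc_in_water,
                                 thc_surface, thc_internal,
                                 oil_recovered, oil_absorbed,
                                 water_dissolved_mg = thc_in_water,
                                 water_volume_mL = 0, flags = character()) {
  thc_in_residue <- thc_surface + thc_internal
  structure(list(
    thc_in_oil = thc_in_oil,
    thc_in_water = thc_in_water,
    thc_in_residue = thc_in_residue,
    thc_residue_surface = thc_surface,
    thc_residue_internal = thc_internal,
    oil_recovered = oil_recovered,
    oil_absorbed = oil_absorbed,
    residue_concentration = thc_in_residue / (exp$seed_mass_g / 1000),
    initial_thc_mg = pools$total_thc_mg,
    water_dissolved_mg = water_dissolved_mg,
    water_volume_mL = water_volume_mL,
    flags = flags,
    experiment = exp, pools = pools),
    class = "partition_result")
}

#' Oil-roasting extraction stage
#'
#' Roasts the seeds in oil: the husk-borne (accessible) THC pool approaches
#' its oil/matrix equilibrium split as `1 - exp(-k t)` (first-order in
#' concentration), where the equilibrium fraction is
#' `K m_oil / (K m_oil + m_seed)` with `K` the oil/water partition
#' coefficient. Oil is retained by the seeds up to a fixed absorption capacity
#' (g oil per g seed); only the excess is recovered as free oil. Of the
#' extracted THC, a small documented fraction (`oil_phase_split`) leaves with
#' the recovered oil; the remainder stays in the absorbed-oil/surface pool on
#' the residue, where washing can reach it.
#'
#' @param exp an [extraction_experiment()].
#' @param seed archetype list (see [hemp_seed_archetype()]), or a precomputed
#'   [seed_thc_pools()] list.
#' @param K oil/matrix partition coefficient; default from the bundled THC
#'   record via [partition_coefficient()].
#' @return object of class `partition_result` with THC masses (mg) in oil,
#'   water and residue (surface + internal components), oil masses (g) and
#'   the residue concentration (mg/kg, on a dry seed-solids basis). A
#'   `"no_free_oil"` flag is set when absorption consumes all input oil.
#' @examples
#' roast_extract(extraction_experiment(), hemp_seed_archetype())
#' @export
roast_extract <- function(exp, seed = hemp_seed_archetype(),
                          K = partition_coefficient(cannabinoid_properties("THC"))) {
  stopifnot(inherits(exp, "extraction_experiment"), K >= 0)
  pools <- if (!is.null(seed$total_thc_mg)) seed
           else seed_thc_pools(exp$seed_mass_g, seed)
  oil_in <- exp$oil_fraction * exp$seed_mass_g
  oil_absorbed <- min(oil_in, exp$oil_absorption_g_per_g * exp$seed_mass_g)
  oil_recovered <- oil_in - oil_absorbed
  flags <- character()
  if (oil_recovered <= 1e-12) flags <- c(flags, "no_free_oil")

  q_eq <- if (is.infinite(K)) 1 else K * oil_in / (K * oil_in + exp$seed_mass_g)
  extent <- (1 - exp(-exp$k_per_min * exp$duration_min)) * q_eq
  extracted <- pools$husk_thc_mg * extent

  to_free_oil <- if (oil_recovered > 1e-12) extracted * exp$oil_phase_split
                 else 0
  thc_surface <- extracted - to_free_oil
  thc_internal <- (pools$husk_thc_mg - extracted) + pools$kernel_thc_mg

  new_partition_result(exp, pools,
                       thc_in_oil = to_free_oil, thc_in_water = 0,
                       thc_surface = thc_surface, thc_internal = thc_internal,
                       oil_recovered = oil_recovered,
                       oil_absorbed = oil_absorbed,
                       water_dissolved_mg = 0, water_volume_mL = 0,
                       flags = flags)
}

#' One water-wash cycle
#'
#' Re-partitions the hydrophilic surface pool between the residue and the wash
#' water. Per cycle, `wash_efficiency` of the surface pool is contacted; the
#' transfer is capped by the aqueous solubility of THC (2.8 mg/L): the water
#' phase can never hold more than `solubility x volume`. With `reuse = TRUE`
#' the same water accumulates solute across cycles and the cap binds on the
#' cumulative load, so reuse removes at most what fresh water would.
#'
#' @param state a `partition_result` from [roast_extract()] or a previous
#'   wash.
#' @param water_volume_mL wash water volume (default four times the seed mass,
#'   1 g = 1 mL).
#' @param reuse logical; reuse the accumulated wash water instead of fresh.
#' @param props solute record supplying the solubility cap (default THC).
#' @return updated `partition_result`; `thc_in_water` is cumulative across
#'   cycles.
#' @export
wash_cycle <- function(state, water_volume_mL = NULL, reuse = NULL,
                       props = cannabinoid_properties("THC")) {
  stopifnot(inherits(state, "partition_result"))
  exp <- state$experiment
  if (is.null(water_volume_mL)) {
    water_volume_mL <- exp$wash_water_ratio * exp$seed_mass_g
  }
  if (is.null(reuse)) reuse <- exp$reuse_water
  stopifnot(water_volume_mL > 0)

  dissolved <- if (reuse) state$water_dissolved_mg else 0
  capacity_mg <- max(0, props$water_solubility_mg_L *
                          (water_volume_mL / 1000) - dissolved)
  contacted <- state$thc_residue_surface * exp$wash_efficiency
  moved <- min(contacted, capacity_mg)

  new_partition_result(
    exp, state$pools,
    thc_in_oil = state$thc_in_oil,
    thc_in_water = state$thc_in_water + moved,
    thc_surface = state$thc_residue_surface - moved,
    thc_internal = state$thc_residue_internal,
    oil_recovered = state$oil_recovered,
    oil_absorbed = state$oil_absorbed,
    water_dissolved_mg = dissolved + moved,
    water_volume_mL = water_volume_mL,
    flags = state$flags)
}

#' Analyte mass in an analysed aliquot of the final wash
#'
#' The protocol tops the final washing solution up to a fixed volume and
#' analyses a small aliquot; the analyte mass in the aliquot scales by
#' `aliquot / final_volume`.
#'
#' @param state a `partition_result` after washing.
#' @param final_volume_mL final washing-solution volume (default 20).
#' @param aliquot_mL analysed aliquot (default 1).
#' @return list with `aliquot_thc_mg` and `aliquot_fraction`.
#' @export
wash_aliquot <- function(state, final_volume_mL = 20, aliquot_mL = 1) {
  stopifnot(inherits(state, "partition_result"),
            final_volume_mL > 0, aliquot_mL > 0,
            aliquot_mL <= final_volume_mL)
  frac <- aliquot_mL / final_volume_mL
  list(aliquot_thc_mg = state$water_dissolved_mg * frac,
       aliquot_fraction = frac)
}

#' Run the full roast-and-wash protocol
#'
#' Executes the oil-roasting stage followed by the configured number of wash
#' cycles and returns the ordered stage results. THC mass is conserved across
#' the whole protocol; the residue concentration is computed on the dry
#' seed-solids mass.
#'
#' @param exp an [extraction_experiment()].
#' @param seed archetype list (default [hemp_seed_archetype()]).
#' @param K oil/matrix partition coefficient (default from THC logP).
#' @return object of class `protocol_report`: list with `stages` (named list
#'   of `partition_result`s: `roast`, `wash_1`, ...), `final` (last stage) and
#'   `mass_balance_error` (relative).
#' @examples
#' run_protocol(extraction_experiment(), hemp_seed_archetype())
#' @export
run_protocol <- function(exp, seed = hemp_seed_archetype(),
                         K = partition_coefficient(cannabinoid_properties("THC"))) {
  state <- roast_extract(exp, seed, K = K)
  stages <- list(roast = state)
  if (exp$wash_cycles > 0) {
    for (i in seq_len(exp$wash_cycles)) {
      state <- wash_cycle(state)
      stages[[paste0("wash_", i)]] <- state
    }
  }
  total <- state$thc_in_oil + state$thc_in_water + state$thc_in_residue
  mbe <- if (state$initial_thc_mg > 0) {
    abs(total - state$initial_thc_mg) / state$initial_thc_mg
  } else abs(total)
  structure(list(stages = stages, final = state, mass_balance_error = mbe),
            class = "protocol_report")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Partition result (THC, mg):\n")
  cat(sprintf("  free oil : %.5f    water : %.5f\n",
              x$thc_in_oil, x$thc_in_water))
  cat(sprintf("  residue  : %.5f (surface %.5f + internal %.5f)\n",
              x$thc_in_residue, x$thc_residue_surface,
              x$thc_residue_internal))
  cat(sprintf("  residue concentration: %.3f mg/kg\n",
              x$residue_concentration))
  cat(sprintf("  oil recovered %.3f g, absorbed %.3f g\n",
              x$oil_recovered, x$oil_absorbed))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("Roast + %d wash cycle(s); mass-balance error %.2e\n",
              length(x$stages) - 1L, x$mass_balance_error))
  print(x$final)
  invisible(x)
}
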