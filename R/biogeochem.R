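# Scalar soil nitrogen biogeochemistry calculators: net nitrification and
# immobilization rates over an incubation, plant 15N recovery and uptake,
# and fertilizer amendment unit conversions.

MOLAR_MASS_N <- 14.0067  # g/mol

#' Inorganic nitrogen pools at a time point
#'
#' @param nh4 Ammonium-N, ug N per g dry soil.
#' @param no3 Nitrate-N, ug N per g dry soil.
#' @param time Time of measurement, days from incubation start.
#' @return List of class \code{n_pools}.
#' @export
n_pools <- function(nh4, no3, time) {
  if (nh4 < 0 || no3 < 0) stop("pools must be non-negative")
  structure(list(nh4 = nh4, no3 = no3, time = time), class = "n_pools")
}

#' Net nitrification rate
#'
#' Change in the nitrate pool per day over an incubation; negative values
#' indicate net nitrate consumption.
#'
#' @param initial,final \code{n_pools} at the start and end of the incubation.
#' @return Rate in ug N per g dry soil per day.
#' @export
net_nitrification_rate <- function(initial, final) {
  dt <- final$time - initial$time
  if (dt <= 0) stop("final time must be after initial time")
  (final$no3 - initial$no3) / dt
}

#' Net immobilization rate
#'
#' Net disappearance of total inorganic N (ammonium + nitrate, including the
#' fertilizer amendment added at the start) per day. Positive values indicate
#' net immobilization into microbial biomass and organic pools; negative
#' values indicate net mineralization.
#'
#' @param initial,final \code{n_pools} at the start and end of the incubation.
#' @param n_added Amendment added at the start, ug N per g dry soil
#'   (default 0).
#' @return Rate in ug N per g dry soil per day.
#' @export
net_immobilization_rate <- function(initial, final, n_added = 0) {
  dt <- final$time - initial$time
  if (dt <= 0) stop("final time must be after initial time")
  if (n_added < 0) stop("n_added must be non-negative")
  ((initial$nh4 + initial$no3 + n_added) - (final$nh4 + final$no3)) / dt
}

#' Plant recovery of the added 15N label
#'
#' @param excess_15n_in_plant Excess 15N recovered in plant biomass (any mass
#'   unit).
#' @param added_15n Total 15N added (same unit).
#' @return Percent of the added label recovered in the plant.
#' @export
plant_15n_recovery <- function(excess_15n_in_plant, added_15n) {
  if (added_15n <= 0) stop("added_15n must be positive")
  100 * excess_15n_in_plant / added_15n
}

#' Plant nitrogen uptake rate from 15N enrichment
#'
#' \code{(atom\% excess of sample x total N) / (atom\% excess of the applied
#' label x incubation time)}. The reference enrichment is that of the applied
#' tracer (e.g. 98 atom\% for a 98\% labeled ammonium sulfate solution).
#'
#' @param atom_pct_excess_sample Atom percent excess 15N of the plant sample.
#' @param total_n Total N in the sample, g N.
#' @param atom_pct_excess_reference Atom percent excess of the applied label.
#' @param time Incubation time, days.
#' @return Uptake rate, g N per day.
#' @export
uptake_rate <- function(atom_pct_excess_sample, total_n,
                        atom_pct_excess_reference, time) {
  if (atom_pct_excess_reference <= 0 || time <= 0) {
    stop("reference enrichment and time must be positive")
  }
  (atom_pct_excess_sample * total_n) / (atom_pct_excess_reference * time)
}

#' Fertilizer amendment unit conversions
#'
#' Converts a molar N amendment per gram of soil to a mass concentration and,
#' given an incorporation depth and soil bulk density, to an areal
#' application rate.
#'
#' @param n_conc Amendment, umol N per g dry soil.
#' @param depth Incorporation depth, cm (needed for the areal rate).
#' @param bulk_density Soil bulk density, g/cm^3.
#' @return List with \code{ug_per_g} (ug N per g soil) and \code{kg_per_ha}
#'   (kg N per hectare; \code{NA} if depth or bulk density not given).
#' @export
amendment_units <- function(n_conc, depth = NULL, bulk_density = NULL) {
  if (n_conc < 0) stop("n_conc must be non-negative")
  ug_per_g <- n_conc * MOLAR_MASS_N
  kg_per_ha <- if (is.null(depth) || is.null(bulk_density)) {
    NA_real_
  } else {
    if (depth <= 0 || bulk_density <= 0) stop("depth and bulk_density must be positive")
    # ug/g * g/cm^3 * cm = ug/cm^2; x 1e8 cm^2/ha x 1e-9 kg/ug
    ug_per_g * bulk_density * depth * 1e8 * 1e-9
  }
  list(ug_per_g = ug_per_g, kg_per_ha = kg_per_ha)
}
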