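# Temperature- and salinity-dependent N2O solubility and the
# headspace-equilibration conversion to dissolved concentration.

# ln(sol) = a1 + a2*(100/T) + a3*ln(T/100) [+ a4*(T/100)^2]
#           + S*(b1 + b2*(T/100) + b3*(T/100)^2), T in kelvin, S in PSU.
# "K0": equilibrium solubility, mol L-1 atm-1 of dry-gas partial pressure.
# "F" : solubility from water-vapour-saturated air at 1 atm total pressure,
#       mol L-1 atm-1 per dry mole fraction.
N2O_SOL_COEF <- list(
  K0 = c(a1 = -62.7062, a2 = 97.3066, a3 = 24.1406, a4 = 0,
         b1 = -0.058420, b2 = 0.033193, b3 = -0.0051313),
  F  = c(a1 = -165.8806, a2 = 222.8743, a3 = 92.0792, a4 = -1.48425,
         b1 = -0.056235, b2 = 0.031619, b3 = -0.0048472)
)

check_ts_range <- function(temperature, salinity) {
  if (any(temperature < -2 | temperature > 40)) {
    stop("temperature outside the -2..40 degC validity range", call. = FALSE)
  }
  if (any(salinity < 0 | salinity > 42)) {
    stop("salinity outside the 0..42 validity range", call. = FALSE)
  }
}

#' N2O solubility in seawater
#'
#' Equilibrium solubility of N2O as a function of temperature and salinity,
#' using the classical marine-chemistry fit with a temperature polynomial and a
#' salting-out term. Two forms are available: `"K0"`, the solubility per
#' atmosphere of dry-gas partial pressure, and `"F"` (default), the solubility
#' from moist air at 1 atm total pressure per dry mole fraction, which builds
#' in the water-vapour correction used when equilibrating a headspace against
#' seawater.
#'
#' @param temperature water temperature, degrees Celsius, in -2..40.
#' @param salinity practical salinity, 0..42.
#' @param form `"F"` (moist air, default) or `"K0"` (dry partial pressure).
#' @return solubility in mol L-1 atm-1; strictly positive and strictly
#'   decreasing in both temperature and salinity over the validity range.
#' @export
n2o_solubility <- function(temperature, salinity, form = c("F", "K0")) {
  form <- match.arg(form)
  check_ts_range(temperature, salinity)
  k <- N2O_SOL_COEF[[form]]
  tk <- (temperature + 273.15) / 100
  exp(k[["a1"]] + k[["a2"]] / tk + k[["a3"]] * log(tk) + k[["a4"]] * tk^2 +
        salinity * (k[["b1"]] + k[["b2"]] * tk + k[["b3"]] * tk^2))
}

#' Vapour pressure of seawater
#'
#' @param temperature degrees Celsius.
#' @param salinity practical salinity.
#' @return water vapour pressure in atm.
#' @export
seawater_vapor_pressure <- function(temperature, salinity) {
  tk <- (temperature + 273.15) / 100
  exp(24.4543 - 67.4509 / tk - 4.8489 * log(tk) - 0.000544 * salinity)
}

#' Describe a headspace equilibration
#'
#' @param temperature equilibration temperature, degrees Celsius.
#' @param salinity sample salinity, PSU.
#' @param water_volume,headspace_volume volumes in mL, `> 0`.
#' @param headspace_ppmv N2O dry mole fraction in the equilibrated headspace,
#'   ppmv, `>= 0`.
#' @return a list of class `"n2o_equilibration"`.
#' @export
equilibration_setup <- function(temperature, salinity, water_volume,
                                headspace_volume, headspace_ppmv) {
  check_ts_range(temperature, salinity)
  if (water_volume <= 0 || headspace_volume <= 0) {
    stop("volumes must be > 0", call. = FALSE)
  }
  if (headspace_ppmv < 0) stop("headspace_ppmv must be >= 0", call. = FALSE)
  structure(list(temperature = temperature, salinity = salinity,
                 water_volume = water_volume,
                 headspace_volume = headspace_volume,
                 headspace_ppmv = headspace_ppmv),
            class = "n2o_equilibration")
}

GAS_CONSTANT_L_ATM <- 0.082057366  # L atm mol-1 K-1

# headspace moles of N2O (mol) at 1 atm total pressure, moist headspace
headspace_moles <- function(setup) {
  p_dry <- 1 - seawater_vapor_pressure(setup$temperature, setup$salinity)
  setup$headspace_ppmv * 1e-6 * p_dry * (setup$headspace_volume / 1000) /
    (GAS_CONSTANT_L_ATM * (setup$temperature + 273.15))
}

#' Dissolved N2O from an equilibrated headspace
#'
#' Converts the measured headspace mole fraction after equilibration to the
#' dissolved N2O concentration in the water phase at equilibrium,
#' `C = F(T, S) * x' * P` with total pressure fixed at 1 atm (moist-air
#' solubility, so the water-vapour correction is included). The conversion is
#' exactly linear in the mole fraction and returns 0 for 0 ppmv.
#'
#' @param setup an [equilibration_setup()].
#' @return dissolved N2O at equilibrium, nmol L-1.
#' @export
headspace_to_dissolved <- function(setup) {
  stopifnot(inherits(setup, "n2o_equilibration"))
  f <- n2o_solubility(setup$temperature, setup$salinity, form = "F")
  f * setup$headspace_ppmv * 1e-6 * 1e9
}

#' Total N2O in a closed equilibration vessel
#'
#' Mass balance companion to [headspace_to_dissolved()]: dissolved moles plus
#' headspace moles at equilibrium. Used to verify that the partitioning is a
#' closed-system inversion.
#'
#' @param setup an [equilibration_setup()].
#' @return total N2O in the vessel, nmol.
#' @export
total_n2o_nmol <- function(setup) {
  stopifnot(inherits(setup, "n2o_equilibration"))
  dissolved <- headspace_to_dissolved(setup) * setup$water_volume / 1000
  dissolved + headspace_moles(setup) * 1e9
}

#' Equilibrium headspace mole fraction for a known N2O amount
#'
#' Inverts the closed-system partition: given the total N2O present in the
#' vessel, returns the headspace dry mole fraction after equilibration. The
#' partition is linear, so this is exact.
#'
#' @param total_nmol total N2O in the vessel, nmol.
#' @param setup an [equilibration_setup()] (its `headspace_ppmv` is ignored).
#' @return equilibrated headspace N2O, ppmv.
#' @export
equilibrium_headspace_ppmv <- function(total_nmol, setup) {
  stopifnot(inherits(setup, "n2o_equilibration"))
  unit <- equilibration_setup(setup$temperature, setup$salinity,
                              setup$water_volume, setup$headspace_volume,
                              headspace_ppmv = 1)
  total_nmol / total_n2o_nmol(unit)
}
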