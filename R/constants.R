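#' Fixed isotope fractionation and physical constants
#'
#' Returns the set of constant fractionation factors used by the
#' discrimination models, together with physical conversion constants.
#' Values (per mil): `a` = 4.4 (CO2 diffusion through stomata), `a_m` = 1.8
#' (dissolution and diffusion through the mesophyll), `b` = 30 (effective
#' RuBisCO carboxylation), `b_bar` = 28 (lumped value absorbing the missing
#' mesophyll term), `b_prime` = 27 (lumped value absorbing both the mesophyll
#' and photorespiration terms), `f` = 12 (photorespiration).
#'
#' @param ... named overrides for individual constants (rarely needed; the
#'   global-run convention replacing the lumped 27/28 values by `b` = 30 is
#'   handled by the discrimination functions' `b` arguments).
#' @return An object of class `photo_constants`: a named list with fields
#'   `a`, `a_m`, `b`, `b_bar`, `b_prime`, `f`, `carbon_mass_conv` (kg C per
#'   mol CO2, 0.012), `diffusivity_ratio` (H2O:CO2 conductance ratio, 1.6)
#'   and `R_gas` (J K-1 mol-1).
#' @export
#' @examples
#' photo_constants()$b_prime  # 27
photo_constants <- function(...) {
  pc <- list(
    a = 4.4, a_m = 1.8, b = 30, b_bar = 28, b_prime = 27, f = 12,
    carbon_mass_conv = 0.012, diffusivity_ratio = 1.6, R_gas = 8.314
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(pc))
    if (length(bad)) stop("unknown photo constant(s): ", paste(bad, collapse = ", "))
    pc[names(over)] <- over
  }
  stopifnot(all(unlist(pc) > 0), pc$b > pc$b_bar, pc$b_bar > pc$b_prime,
            pc$b_prime > pc$a)
  class(pc) <- "photo_constants"
  pc
}

# Reference state for all Arrhenius responses: 25 degC and 99.1 kPa.
T_REF_K <- 298.15
P_REF_PA <- 99100

#' Photosynthetic kinetic parameter sets
#'
#' Temperature-response constants for the CO2 compensation point and the
#' RuBisCO Michaelis constants, referenced to 25 degC and 99.1 kPa. Two
#' variants are available and never mixed within one evaluation:
#' `"infinite_gm"` uses intercellular-CO2-based kinetics (Bernacchi et al.
#' 2001), appropriate when mesophyll conductance is taken as infinite;
#' `"finite_gm"` uses chloroplastic-CO2-based kinetics (Bernacchi et al.
#' 2002) for the finite-mesophyll model variants.
#'
#' @param variant `"infinite_gm"` or `"finite_gm"`.
#' @return An object of class `kinetic_params`: named list with
#'   `gamma_star_25` and `Kc_25` (umol mol-1), `Ko_25` (mmol mol-1), the
#'   matching activation energies (J mol-1) and the `variant` tag.
#' @export
#' @examples
#' kinetic_params()$gamma_star_25        # 42.75
#' kinetic_params("finite_gm")$gamma_star_25  # 37.43
kinetic_params <- function(variant = c("infinite_gm", "finite_gm")) {
  variant <- match.arg(variant)
  kp <- switch(variant,
    infinite_gm = list(
      gamma_star_25 = 42.75, Ea_gamma_star = 37830,
      Kc_25 = 404.9, Ea_Kc = 79430,
      Ko_25 = 278.4, Ea_Ko = 36380
    ),
    finite_gm = list(
      gamma_star_25 = 37.43, Ea_gamma_star = 24460,
      Kc_25 = 272.38, Ea_Kc = 80990,
      Ko_25 = 165.82, Ea_Ko = 23720
    )
  )
  kp$variant <- variant
  stopifnot(kp$gamma_star_25 > 0, kp$Kc_25 > 0)
  class(kp) <- "kinetic_params"
  kp
}

#' Arrhenius temperature response
#'
#' Scales a quantity from its 25 degC reference value using
#' `x(T) = x25 * exp(Ea * (T - Tref) / (Tref * R * T))`, the standard
#' exponential response for photosynthetic kinetic parameters. Exact at
#' the reference temperature; log-linear in -1/T.
#'
#' @param x25 value at 298.15 K.
#' @param Ea activation energy, J mol-1.
#' @param T_K temperature, K (vectorised).
#' @return value(s) at `T_K`, same units as `x25`.
#' @export
arrhenius <- function(x25, Ea, T_K) {
  check_temperature(T_K)
  x25 * exp(Ea * (T_K - T_REF_K) / (T_REF_K * 8.314 * T_K))
}

check_temperature <- function(T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 240) || any(T_K >= 340))
    stop("leaf temperature out of physiological domain (240, 340) K")
  invisible(T_K)
}

#' CO2 compensation point
#'
#' The CO2 compensation point in the absence of dark respiration, Gamma*,
#' at a given leaf temperature, from its reference value at 25 degC and
#' 99.1 kPa via an Arrhenius response. Returned as a mole fraction
#' (umol mol-1), which is pressure-invariant; use [mole_frac_to_pa()] for
#' the partial-pressure form, which scales linearly with total pressure.
#'
#' @param T_leaf leaf temperature, K.
#' @param params a [kinetic_params()] set.
#' @return Gamma* in umol mol-1.
#' @export
#' @examples
#' gamma_star(298.15)  # 42.75 by construction
gamma_star <- function(T_leaf, params = kinetic_params()) {
  arrhenius(params$gamma_star_25, params$Ea_gamma_star, T_leaf)
}

#' Effective Michaelis constant for RuBisCO-limited photosynthesis
#'
#' `K = Kc * (1 + O / Ko)` where Kc and Ko follow Arrhenius responses and
#' O is the oxygen mole fraction. Increasing in both temperature and O.
#'
#' @param T_leaf leaf temperature, K.
#' @param O2 oxygen mole fraction, mmol mol-1 (default 210, ambient air).
#' @param params a [kinetic_params()] set.
#' @return K in umol mol-1.
#' @export
michaelis_K <- function(T_leaf, O2 = 210, params = kinetic_params()) {
  if (any(O2 < 0)) stop("oxygen mole fraction must be non-negative")
  Kc <- arrhenius(params$Kc_25, params$Ea_Kc, T_leaf)
  Ko <- arrhenius(params$Ko_25, params$Ea_Ko, T_leaf)
  Kc * (1 + O2 / Ko)
}

#' Unit helpers: mole fraction vs partial pressure
#'
#' Converts between mole fractions (umol mol-1) and partial pressures (Pa)
#' at a given total pressure. The model works internally in mole fractions;
#' these helpers centralise the pressure conversion.
#'
#' @param x mole fraction, umol mol-1 (or partial pressure, Pa, for the
#'   inverse).
#' @param pressure total pressure, Pa.
#' @return converted value.
#' @export
mole_frac_to_pa <- function(x, pressure) {
  if (any(pressure <= 0)) stop("pressure must be positive")
  x * 1e-6 * pressure
}

#' @rdname mole_frac_to_pa
#' @export
pa_to_mole_frac <- function(x, pressure) {
  if (any(pressure <= 0)) stop("pressure must be positive")
  x / (1e-6 * pressure)
}

#' Saturation vapor pressure (Magnus form)
#'
#' `e_sat = 0.61094 * exp(17.625 * Tc / (Tc + 243.04))` kPa with Tc in degC
#' (Alduchov & Eskridge 1996 coefficients). Used to couple vapor pressure
#' deficit to temperature in the synthetic forcing and in humidity
#' conversions.
#'
#' @param T_K temperature, K.
#' @return saturation vapor pressure, kPa.
#' @export
sat_vapor_pressure <- function(T_K) {
  Tc <- T_K - 273.15
  0.61094 * exp(17.625 * Tc / (Tc + 243.04))
}

#' Specific humidity deficit from vapor pressure deficit
#'
#' Approximate conversion `d_q = 0.622 * D / (P - e)` (kg kg-1) with D and
#' e in the same pressure units as P; the small vapor correction in the
#' denominator is retained.
#'
#' @param D vapor pressure deficit, kPa.
#' @param T_K air temperature, K.
#' @param pressure total pressure, Pa.
#' @return specific humidity deficit, kg kg-1.
#' @export
vpd_to_specific_humidity_deficit <- function(D, T_K, pressure) {
  e_act <- pmax(sat_vapor_pressure(T_K) - D, 0)   # kPa
  0.622 * (D * 1000) / (pressure - e_act * 1000)
}
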