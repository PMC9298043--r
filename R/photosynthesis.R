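#' Plant-functional-type parameter set
#'
#' Bundles the PFT-dependent parameters of the photosynthesis and stomatal
#' closure models. Defaults are literature-typical values for a temperate
#' broadleaf deciduous forest; per-PFT files under
#' `system.file("extdata", "pft_params.csv", package = "isocanopy")` provide
#' stand-in sets for five forest PFTs.
#'
#' @param Vcmax_25 maximum carboxylation rate at 25 degC, umol m-2 s-1.
#' @param Jmax_to_Vcmax Jmax:Vcmax ratio at 25 degC.
#' @param f_d dark respiration fraction, Rd = f_d * Vcmax.
#' @param quantum_yield mol electrons per mol photons.
#' @param curvature_J non-rectangular hyperbola shape for electron transport.
#' @param curvature_W co-limitation smoothing between carboxylation- and
#'   light-limited rates.
#' @param f_0 Jacobs ci/ca at zero specific humidity deficit.
#' @param dq_crit critical specific humidity deficit, kg kg-1.
#' @param g1 Medlyn slope, kPa^0.5.
#' @param a1,D0,g0 Leuning parameters (unitless, kPa, mol m-2 s-1).
#' @param beta_cost Prentice least-cost unit-cost ratio (infinite gm).
#' @param beta_cost_c finite-gm counterpart of `beta_cost`.
#' @param gsc_over_gm fixed stomatal:mesophyll conductance ratio.
#' @param LAI leaf area index, m2 m-2.
#' @param g_night nighttime minimum (cuticular) conductance, mol m-2 s-1.
#' @return an object of class `pft_params` (named list).
#' @export
pft_params <- function(Vcmax_25 = 50, Jmax_to_Vcmax = 1.9, f_d = 0.015,
                       quantum_yield = 0.3, curvature_J = 0.7,
                       curvature_W = 0.9, f_0 = 0.875, dq_crit = 0.09,
                       g1 = 4.45, a1 = 9, D0 = 1.5, g0 = 0,
                       beta_cost = 146, beta_cost_c = 218.6,
                       gsc_over_gm = 0.25, LAI = 5, g_night = 0.003) {
  p <- list(Vcmax_25 = Vcmax_25, Jmax_to_Vcmax = Jmax_to_Vcmax, f_d = f_d,
            quantum_yield = quantum_yield, curvature_J = curvature_J,
            curvature_W = curvature_W, f_0 = f_0, dq_crit = dq_crit,
            g1 = g1, a1 = a1, D0 = D0, g0 = g0, beta_cost = beta_cost,
            beta_cost_c = beta_cost_c, gsc_over_gm = gsc_over_gm,
            LAI = LAI, g_night = g_night)
  num <- unlist(p[setdiff(names(p), "g0")])
  stopifnot(all(num > 0), p$g0 >= 0, f_0 < 1,
            curvature_J <= 1, curvature_W <= 1)
  class(p) <- "pft_params"
  p
}

#' Load PFT parameter sets shipped with the package
#'
#' Reads the per-PFT parameter table (one row per forest PFT) and returns
#' the requested set as a [pft_params()] object. These values are editable
#' stand-ins with literature-typical magnitudes, not a calibrated product.
#'
#' @param pft one of `"BET-Tr"`, `"BET-Te"`, `"BDT"`, `"NET"`, `"NDT"`
#'   (tropical/temperate broadleaf evergreen, broadleaf deciduous,
#'   needle-leaf evergreen/deciduous trees).
#' @param file optional path to an alternative parameter table with the
#'   same columns.
#' @return a [pft_params()] object.
#' @export
load_pft_params <- function(pft = "BDT", file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "pft_params.csv", package = "isocanopy")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  row <- tab[tab$pft == pft, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown PFT: ", pft)
  do.call(pft_params, as.list(row[, setdiff(names(row), "pft")]))
}

#' Vcmax, Jmax and dark respiration at leaf temperature
#'
#' Standard Arrhenius response with a peaked (entropy-based) deactivation
#' term for Vcmax and Jmax; Rd is proportional to Vcmax at the same
#' temperature through the PFT parameter `f_d`.
#'
#' @param T_leaf leaf temperature, K.
#' @param pft a [pft_params()] object.
#' @return list with `Vcmax`, `Jmax`, `Rd` in umol m-2 s-1.
#' @export
kinetic_rates <- function(T_leaf, pft = pft_params()) {
  check_temperature(T_leaf)
  peaked <- function(x25, Ea, Hd, S) {
    f25 <- 1 + exp((S * T_REF_K - Hd) / (8.314 * T_REF_K))
    fT <- 1 + exp((S * T_leaf - Hd) / (8.314 * T_leaf))
    arrhenius(x25, Ea, T_leaf) * f25 / fT
  }
  Vcmax <- peaked(pft$Vcmax_25, 65330, 2e5, 640)
  Jmax <- peaked(pft$Vcmax_25 * pft$Jmax_to_Vcmax, 43540, 2e5, 647)
  list(Vcmax = Vcmax, Jmax = Jmax, Rd = pft$f_d * Vcmax)
}

#' RuBisCO-limited (carboxylation) assimilation rate
#'
#' `A_C = Vcmax * (ci - Gamma*) / (ci + K)`: zero at the compensation
#' point, saturating towards Vcmax at high ci.
#'
#' @param Vcmax maximum carboxylation rate, umol m-2 s-1.
#' @param ci intercellular (or chloroplastic) CO2, umol mol-1.
#' @param gamma_star CO2 compensation point, umol mol-1.
#' @param K effective Michaelis constant, umol mol-1.
#' @return A_C, umol m-2 s-1 (negative below the compensation point).
#' @export
carboxylation_rate <- function(Vcmax, ci, gamma_star, K) {
  if (any(ci < 0)) stop("ci must be non-negative")
  Vcmax * (ci - gamma_star) / (ci + K)
}

#' Electron-transport-limited assimilation rate
#'
#' The electron transport rate J is the smaller root of the
#' non-rectangular hyperbola
#' `theta J^2 - (alpha Q + Jmax) J + alpha Q Jmax = 0`
#' in the absorbed light `alpha Q` and `Jmax`; the assimilation rate is
#' `A_J = J (ci - Gamma*) / (4 ci + 8 Gamma*)`.
#'
#' @param PPFD photosynthetic photon flux density, umol m-2 s-1.
#' @param Jmax maximum electron transport rate, umol m-2 s-1.
#' @param ci intercellular CO2, umol mol-1.
#' @param gamma_star CO2 compensation point, umol mol-1.
#' @param pft a [pft_params()] object (quantum yield and J curvature).
#' @return A_J, umol m-2 s-1.
#' @export
light_limited_rate <- function(PPFD, Jmax, ci, gamma_star, pft = pft_params()) {
  if (any(PPFD < 0)) stop("PPFD must be non-negative")
  J <- smaller_quadratic_root(pft$curvature_J,
                              pft$quantum_yield * PPFD, Jmax)
  J * (ci - gamma_star) / (4 * ci + 8 * gamma_star)
}

# Smaller root of theta x^2 - (p + q) x + p q = 0, numerically safe form.
# For theta = 1 it degenerates to min(p, q); for theta -> 0 to p q/(p + q).
smaller_quadratic_root <- function(theta, p, q) {
  if (theta <= 0 || theta > 1) stop("curvature must lie in (0, 1]")
  s <- p + q
  disc <- pmax(s^2 - 4 * theta * p * q, 0)
  # 2pq / (s + sqrt(disc)) avoids cancellation and handles theta = 1 at p = q
  out <- 2 * p * q / (s + sqrt(disc))
  out[s == 0] <- 0
  out
}

#' Smoothed minimum of two limiting rates
#'
#' The gross rate W is the smaller root of
#' `theta W^2 - (A_C + A_J) W + A_C A_J = 0`, a symmetric co-limitation
#' that approaches `min(A_C, A_J)` as the curvature tends to 1.
#'
#' @param A_C,A_J limiting rates, umol m-2 s-1.
#' @param curvature_W co-limitation shape in (0, 1].
#' @return W, umol m-2 s-1, with `W <= min(A_C, A_J)` for positive rates.
#' @export
smoothed_min <- function(A_C, A_J, curvature_W = 0.9) {
  smaller_quadratic_root(curvature_W, A_C, A_J)
}

#' Net assimilation under soil water stress
#'
#' `A_n = (W - Rd) * beta_soil`: respiration is subtracted before the
#' dimensionless soil water stress factor scales the net rate, so that the
#' canopy carbon balance (gross uptake as net plus stressed respiration)
#' stays internally consistent.
#'
#' @param W gross (smoothed-minimum) rate, umol m-2 s-1.
#' @param Rd dark respiration, umol m-2 s-1.
#' @param beta_soil soil water stress factor in \[0, 1\].
#' @return A_n, umol m-2 s-1.
#' @export
net_assimilation <- function(W, Rd, beta_soil) {
  if (any(beta_soil < 0 | beta_soil > 1)) stop("beta_soil must lie in [0, 1]")
  if (any(Rd < 0)) stop("Rd must be non-negative")
  (W - Rd) * beta_soil
}
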