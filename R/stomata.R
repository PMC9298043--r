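#' Meteorological state series constructor
#'
#' Builds the per-timestep environmental driver table consumed by the leaf
#' and canopy routines. All arguments are recycled to a common length.
#' Leaf temperature defaults to air temperature (no leaf energy balance);
#' the specific humidity deficit defaults to a conversion from `D` at the
#' given pressure.
#'
#' @param T_air air temperature, K.
#' @param D leaf-to-air vapor pressure deficit, kPa.
#' @param PPFD photosynthetic photon flux density, umol m-2 s-1.
#' @param c_a ambient CO2, umol mol-1.
#' @param pressure atmospheric pressure, Pa.
#' @param T_leaf leaf temperature, K (default `T_air`).
#' @param d_q specific humidity deficit, kg kg-1 (default from `D`).
#' @param precip precipitation, mm per timestep.
#' @param timestamp POSIXct or numeric time axis.
#' @return a `data.frame` of class `met_state`.
#' @export
met_state <- function(T_air, D, PPFD, c_a, pressure = 101325,
                      T_leaf = T_air, d_q = NULL, precip = 0,
                      timestamp = NULL) {
  if (any(D < 0)) stop("vapor pressure deficit must be non-negative")
  if (any(c_a <= 0)) stop("ambient CO2 must be positive")
  if (any(pressure <= 0)) stop("pressure must be positive")
  if (is.null(d_q)) d_q <- vpd_to_specific_humidity_deficit(D, T_air, pressure)
  args <- list(T_air = T_air, T_leaf = T_leaf, D = D, d_q = d_q,
               PPFD = PPFD, c_a = c_a, pressure = pressure, precip = precip)
  n <- max(lengths(args), length(timestamp))
  out <- as.data.frame(lapply(args, rep_len, n))
  if (!is.null(timestamp)) out$timestamp <- rep_len(timestamp, n)
  class(out) <- c("met_state", "data.frame")
  out
}

#' Jacobs humidity-deficit closure for intercellular CO2
#'
#' `ci = (ca - Gamma*) f0 (1 - dq/dq_crit) + Gamma*`, clipped at Gamma*
#' once the specific humidity deficit exceeds its critical value.
#'
#' @param c_a ambient CO2, umol mol-1.
#' @param gamma_star CO2 compensation point, umol mol-1.
#' @param f_0 ci/ca at zero humidity deficit.
#' @param d_q specific humidity deficit, kg kg-1.
#' @param dq_crit critical humidity deficit, kg kg-1.
#' @return ci, umol mol-1.
#' @export
ci_jacobs <- function(c_a, gamma_star, f_0, d_q, dq_crit) {
  if (any(dq_crit <= 0)) stop("dq_crit must be positive")
  if (any(d_q < 0)) stop("d_q must be non-negative")
  pmax((c_a - gamma_star) * f_0 * (1 - d_q / dq_crit) + gamma_star, gamma_star)
}

#' Medlyn unified stomatal closure for intercellular CO2
#'
#' `ci = ca * g1 / (g1 + sqrt(D))`: stomata regulated to maximise carbon
#' gain per unit water lost, with the slope g1 in kPa^0.5 carrying the
#' square-root dependence on vapor pressure deficit.
#'
#' @param c_a ambient CO2, umol mol-1.
#' @param g1 slope parameter, kPa^0.5.
#' @param D vapor pressure deficit, kPa.
#' @return ci, umol mol-1.
#' @export
ci_medlyn <- function(c_a, g1, D) {
  if (any(g1 <= 0)) stop("g1 must be positive")
  if (any(D < 0)) stop("D must be non-negative")
  c_a * g1 / (g1 + sqrt(D))
}

#' Leuning closure for intercellular CO2
#'
#' Canonical Leuning conductance model
#' `gsc = g0 + a1 * An / ((ca - Gamma*) (1 + D/D0))` solved jointly with
#' the CO2 diffusion relation. For `g0 = 0` the closure has the
#' assimilation-independent closed form
#' `ci = ca - (ca - Gamma*) (1 + D/D0) / a1`, returned directly; the
#' general case is handled inside [solve_leaf()]. Infeasible parameter
#' combinations (`a1 <= 1 + D/D0`) are flagged by returning `ci = Gamma*`
#' with attribute `degenerate = TRUE`.
#'
#' @param c_a ambient CO2, umol mol-1.
#' @param gamma_star CO2 compensation point, umol mol-1.
#' @param a1 stomatal sensitivity (unitless).
#' @param D vapor pressure deficit, kPa.
#' @param D0 humidity sensitivity scale, kPa.
#' @return ci, umol mol-1 (g0 = 0 closed form).
#' @export
ci_leuning <- function(c_a, gamma_star, a1, D, D0) {
  if (any(D0 <= 0)) stop("D0 must be positive")
  hum <- 1 + D / D0
  ci <- c_a - (c_a - gamma_star) * hum / a1
  degen <- a1 <= hum
  ci <- pmax(ci, gamma_star)
  if (any(degen)) attr(ci, "degenerate") <- degen
  ci
}

#' Prentice least-cost optimality closure for intercellular CO2
#'
#' Leaves minimise the summed unit costs of transpiration and
#' carboxylation, giving `ci = Gamma* + (ca - Gamma*) xi / (xi + sqrt(D))`
#' with `xi = sqrt(beta (K + Gamma*) / (1.6 eta*))`; D, K and Gamma* enter
#' in Pa, so the ambient pressure is required for the conversion from mole
#' fractions.
#'
#' @param c_a ambient CO2, umol mol-1.
#' @param gamma_star CO2 compensation point, umol mol-1.
#' @param K effective Michaelis constant, umol mol-1.
#' @param D vapor pressure deficit, kPa.
#' @param beta_cost unit-cost ratio for carboxylation vs transpiration.
#' @param pressure atmospheric pressure, Pa.
#' @param eta_star viscosity of water relative to 25 degC (default 1).
#' @return ci, umol mol-1.
#' @export
ci_prentice <- function(c_a, gamma_star, K, D, beta_cost,
                        pressure = P_REF_PA, eta_star = 1) {
  if (any(beta_cost <= 0)) stop("beta_cost must be positive")
  if (any(D < 0)) stop("D must be non-negative")
  gs_pa <- mole_frac_to_pa(gamma_star, pressure)
  K_pa <- mole_frac_to_pa(K, pressure)
  xi <- sqrt(beta_cost * (K_pa + gs_pa) / (1.6 * eta_star))
  gamma_star + (c_a - gamma_star) * xi / (xi + sqrt(D * 1000))
}

#' Finite-mesophyll least-cost closure for chloroplastic CO2
#'
#' Variant of the least-cost closure predicting chloroplastic CO2 under a
#' fixed stomatal:mesophyll conductance ratio:
#' `xi_c = sqrt(beta_c (Kc + Gammac*) / (1.6 eta* (1 + gsc/gm)))`. With
#' `gsc_over_gm = 0` it reduces to [ci_prentice()] evaluated with the
#' finite-gm (chloroplast-based) kinetic constants.
#'
#' @param c_a ambient CO2, umol mol-1.
#' @param gamma_star_c chloroplast-based CO2 compensation point, umol mol-1.
#' @param K_c chloroplast-based Michaelis constant, umol mol-1.
#' @param D vapor pressure deficit, kPa.
#' @param beta_cost_c finite-gm unit-cost ratio.
#' @param gsc_over_gm stomatal:mesophyll conductance ratio (>= 0).
#' @param pressure atmospheric pressure, Pa.
#' @param eta_star relative viscosity of water (default 1).
#' @return cc, umol mol-1.
#' @export
cc_prentice <- function(c_a, gamma_star_c, K_c, D, beta_cost_c,
                        gsc_over_gm = 0.25, pressure = P_REF_PA,
                        eta_star = 1) {
  if (any(gsc_over_gm < 0)) stop("gsc_over_gm must be non-negative")
  ci_prentice(c_a, gamma_star_c, K_c, D,
              beta_cost_c / (1 + gsc_over_gm), pressure, eta_star)
}

#' Calibrate the finite-gm cost ratio against the infinite-gm closure
#'
#' Returns the `beta_cost_c` for which the chloroplastic closure
#' reproduces the intercellular closure's ci at a reference environment
#' (25 degC, 99.1 kPa, D = 1 kPa by default). Used once to fix the shipped
#' default; exposed so users substituting their own `beta_cost` can redo
#' the calibration.
#'
#' @param beta_cost infinite-gm cost ratio being matched.
#' @param gsc_over_gm stomatal:mesophyll conductance ratio.
#' @param D reference vapor pressure deficit, kPa.
#' @param c_a reference ambient CO2, umol mol-1.
#' @return calibrated `beta_cost_c`.
#' @export
calibrate_beta_cost_c <- function(beta_cost = 146, gsc_over_gm = 0.25,
                                  D = 1, c_a = 400) {
  kin_i <- kinetic_params("infinite_gm")
  kin_f <- kinetic_params("finite_gm")
  target <- ci_prentice(c_a, gamma_star(T_REF_K, kin_i),
                        michaelis_K(T_REF_K, params = kin_i), D, beta_cost)
  gs_c <- gamma_star(T_REF_K, kin_f)
  Kc <- michaelis_K(T_REF_K, params = kin_f)
  # invert the closed form: xi_c from target ci, then beta_c from xi_c
  ratio <- (target - gs_c) / (c_a - gs_c)
  xi_c <- ratio * sqrt(D * 1000) / (1 - ratio)
  xi_c^2 * 1.6 * (1 + gsc_over_gm) /
    (mole_frac_to_pa(Kc + gs_c, P_REF_PA))
}

#' Stomatal conductance from the CO2 diffusion relation
#'
#' `gsc = An / (ca - ci)` in mol m-2 s-1 with An in umol m-2 s-1 and the
#' CO2 gap in umol mol-1.
#'
#' @param A_n net assimilation, umol m-2 s-1.
#' @param c_a,c_i ambient and intercellular CO2, umol mol-1.
#' @return gsc, mol m-2 s-1.
#' @export
stomatal_conductance <- function(A_n, c_a, c_i) {
  gap <- c_a - c_i
  if (any(gap == 0 & A_n != 0))
    stop("degenerate state: ci equals ca with nonzero assimilation")
  out <- A_n / gap
  out[A_n == 0] <- 0
  out
}

#' Intrinsic water-use efficiency
#'
#' `iWUE = (ca - ci) / 1.6`, assimilation per unit stomatal conductance to
#' water; directly tied to ci/ca and hence to isotope discrimination.
#'
#' @param c_a,c_i ambient and intercellular CO2, umol mol-1.
#' @return iWUE, umol mol-1.
#' @export
iwue <- function(c_a, c_i) {
  (c_a - c_i) / 1.6
}

#' Closure selector tokens
#' @keywords internal
CLOSURES <- c("jacobs", "medlyn", "leuning", "prentice", "prentice-cc")

#' Coupled leaf-level solution
#'
#' Solves the leaf photosynthesis system — the chosen intercellular (or
#' chloroplastic) CO2 closure, the Farquhar limiting rates, net
#' assimilation under soil water stress, and the CO2 diffusion relation —
#' simultaneously, and evaluates the three discrimination models at the
#' solution. All meteorological columns are vectorised. For closures whose
#' ci does not depend on assimilation (Jacobs, Medlyn, Prentice and the
#' g0 = 0 Leuning form) the solution is direct; for Leuning with g0 > 0 a
#' bracketed scalar root solve on ci is used per timestep (relative
#' tolerance 1e-8). In the dark (PPFD = 0) the closure is bypassed:
#' `An = -Rd * beta_soil`, ci = ca, and conductance is set to the
#' configured nighttime minimum.
#'
#' @param met a [met_state()] table (one or more rows).
#' @param pft a [pft_params()] object.
#' @param beta_soil soil water stress factor in \[0, 1\] (scalar or
#'   per-timestep).
#' @param closure one of `"jacobs"`, `"medlyn"`, `"leuning"`,
#'   `"prentice"`, `"prentice-cc"`.
#' @param constants a [photo_constants()] set.
#' @param b_carbox carboxylation fractionation convention for the simple
#'   and photorespiratory discrimination models: `"lumped"` (27/28 per mil
#'   defaults) or `"b30"` (30 per mil in all variants, the global-run
#'   convention for model intercomparison).
#' @return a `data.frame` of class `leaf_state` with columns `A_C`, `A_J`,
#'   `W`, `A_n`, `Rd`, `c_i`, `c_c`, `g_sc`, `iWUE`, `delta_simple`,
#'   `delta_photo`, `delta_full`, `closure`.
#' @export
solve_leaf <- function(met, pft = pft_params(), beta_soil = 1,
                       closure = "medlyn", constants = photo_constants(),
                       b_carbox = c("lumped", "b30")) {
  closure <- match.arg(closure, CLOSURES)
  b_carbox <- match.arg(b_carbox)
  n <- nrow(met)
  beta_soil <- rep_len(beta_soil, n)

  finite_gm <- closure == "prentice-cc"
  kin <- kinetic_params(if (finite_gm) "finite_gm" else "infinite_gm")
  gs <- gamma_star(met$T_leaf, kin)
  K <- michaelis_K(met$T_leaf, params = kin)
  rates <- kinetic_rates(met$T_leaf, pft)

  # substrate CO2 seen by RuBisCO: ci (infinite gm) or cc (finite gm)
  cs <- switch(closure,
    jacobs = ci_jacobs(met$c_a, gs, pft$f_0, met$d_q, pft$dq_crit),
    medlyn = ci_medlyn(met$c_a, pft$g1, met$D),
    leuning = ci_leuning(met$c_a, gs, pft$a1, met$D, pft$D0),
    prentice = ci_prentice(met$c_a, gs, K, met$D, pft$beta_cost,
                           met$pressure),
    `prentice-cc` = cc_prentice(met$c_a, gs, K, met$D, pft$beta_cost_c,
                                pft$gsc_over_gm, met$pressure)
  )
  cs <- as.numeric(cs)

  if (closure == "leuning" && pft$g0 > 0)
    cs <- vapply(seq_len(n), function(i)
      leuning_root(met$c_a[i], gs[i], K[i], rates$Vcmax[i], rates$Jmax[i],
                   rates$Rd[i], met$PPFD[i], met$D[i], beta_soil[i], pft),
      numeric(1))

  A_C <- carboxylation_rate(rates$Vcmax, cs, gs, K)
  A_J <- light_limited_rate(met$PPFD, rates$Jmax, cs, gs, pft)
  W <- smoothed_min(A_C, A_J, pft$curvature_W)
  A_n <- net_assimilation(W, rates$Rd, beta_soil)

  if (finite_gm) {
    c_c <- cs
    # fixed gsc/gm ratio r implies ci - cc = r (ca - ci)
    r <- pft$gsc_over_gm
    c_i <- (c_c + r * met$c_a) / (1 + r)
  } else {
    c_i <- cs
    c_c <- cs
  }

  dark <- met$PPFD <= 0
  night_state <- -rates$Rd * beta_soil
  A_n[dark] <- night_state[dark]
  W[dark] <- 0
  c_i[dark] <- met$c_a[dark]
  c_c[dark] <- met$c_a[dark]

  g_sc <- ifelse(dark | A_n <= 0, pft$g_night,
                 A_n / pmax(met$c_a - c_i, 1e-9))

  ratio <- pmin(pmax(c_i / met$c_a, 0), 1)
  b_sim <- if (b_carbox == "b30") constants$b else constants$b_prime
  b_pho <- if (b_carbox == "b30") constants$b else constants$b_bar
  out <- data.frame(
    A_C = A_C, A_J = A_J, W = W, A_n = A_n, Rd = rates$Rd,
    c_i = c_i, c_c = c_c, g_sc = g_sc,
    iWUE = iwue(met$c_a, c_i),
    delta_simple = delta13c_simple(ratio, constants, b_prime = b_sim),
    delta_photo = delta13c_photo(ratio, gs, met$c_a, constants,
                                 b_bar = b_pho),
    delta_full = delta13c_full(c_i, c_c, met$c_a, gs, constants)$delta_full,
    closure = closure
  )
  class(out) <- c("leaf_state", "data.frame")
  out
}

# Bracketed root solve for the Leuning closure with residual conductance:
# find ci where the closure conductance equals the diffusion-law conductance.
leuning_root <- function(c_a, gs, K, Vcmax, Jmax, Rd, PPFD, D, beta_soil,
                         pft, tol = 1e-8) {
  an_at <- function(ci) {
    A_C <- carboxylation_rate(Vcmax, ci, gs, K)
    A_J <- light_limited_rate(PPFD, Jmax, ci, gs, pft)
    net_assimilation(smoothed_min(A_C, A_J, pft$curvature_W), Rd, beta_soil)
  }
  resid <- function(ci) {
    An <- an_at(ci)
    g_cl <- pft$g0 + pft$a1 * An / ((c_a - gs) * (1 + D / pft$D0))
    g_cl * (c_a - ci) - An
  }
  lo <- gs + 1e-6
  hi <- c_a - 1e-6
  if (resid(lo) * resid(hi) > 0) return(max(ci_leuning(c_a, gs, pft$a1, D, pft$D0), gs))
  r <- stats::uniroot(resid, c(lo, hi), tol = tol * c_a, maxiter = 100)
  r$root
}
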