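#' Simple discrimination model
#'
#' `Delta = a + (b' - a) ci/ca` with a = 4.4 and b' = 27 per mil: the
#' lumped two-endmember form in which b' absorbs the (neglected) mesophyll
#' and photorespiration terms. Under the global-run intercomparison
#' convention b' is replaced by b = 30 per mil via the `b_prime` argument.
#'
#' @param ci_over_ca ci/ca ratio in \[0, 1\] (vectorised).
#' @param constants a [photo_constants()] set.
#' @param b_prime effective carboxylation fractionation, per mil.
#' @return Delta13C, per mil.
#' @export
#' @examples
#' delta13c_simple(0.7)  # 20.22
delta13c_simple <- function(ci_over_ca, constants = photo_constants(),
                            b_prime = constants$b_prime) {
  if (any(ci_over_ca < 0 | ci_over_ca > 1)) stop("ci/ca must lie in [0, 1]")
  constants$a + (b_prime - constants$a) * ci_over_ca
}

#' Discrimination model with photorespiration
#'
#' `Delta = a + (b_bar - a) ci/ca - f Gamma*/ca` with b_bar = 28 per mil
#' absorbing the missing mesophyll term and f = 12 per mil the
#' photorespiration fractionation. Gamma* enters as a mole fraction,
#' pressure-consistent with ca.
#'
#' @param ci_over_ca ci/ca ratio in \[0, 1\].
#' @param gamma_star CO2 compensation point, umol mol-1.
#' @param c_a ambient CO2, umol mol-1.
#' @param constants a [photo_constants()] set.
#' @param b_bar effective carboxylation fractionation, per mil.
#' @return Delta13C, per mil.
#' @export
delta13c_photo <- function(ci_over_ca, gamma_star, c_a,
                           constants = photo_constants(),
                           b_bar = constants$b_bar) {
  if (any(ci_over_ca < 0 | ci_over_ca > 1)) stop("ci/ca must lie in [0, 1]")
  if (any(c_a <= 0)) stop("ca must be positive")
  constants$a + (b_bar - constants$a) * ci_over_ca -
    constants$f * gamma_star / c_a
}

#' Full discrimination model with mesophyll and photorespiration terms
#'
#' `Delta = a (ca - ci)/ca + b cc/ca - f Gammac*/ca + a_m (ci - cc)/ca`
#' with a = 4.4, a_m = 1.8, b = 30, f = 12 per mil: diffusion across the
#' stomata, RuBisCO carboxylation at the chloroplast, photorespiration,
#' and dissolution/diffusion through the mesophyll. Requires the
#' chloroplast-based compensation point.
#'
#' @param c_i intercellular CO2, umol mol-1.
#' @param c_c chloroplastic CO2, umol mol-1 (`c_c <= c_i`).
#' @param c_a ambient CO2, umol mol-1.
#' @param gamma_star_c chloroplast-based compensation point, umol mol-1.
#' @param constants a [photo_constants()] set.
#' @return list of class `discrimination_result` with `delta_full` and the
#'   four term fields `term_diffusion`, `term_carboxylation`,
#'   `term_photorespiration`, `term_mesophyll` (each vectorised); the
#'   terms sum to `delta_full` exactly.
#' @export
#' @examples
#' delta13c_full(280, 240, 400, 40)$delta_full  # 18.3
delta13c_full <- function(c_i, c_c, c_a, gamma_star_c,
                          constants = photo_constants()) {
  if (any(c_c > c_i + 1e-9) || any(c_i > c_a + 1e-9))
    stop("CO2 ordering violated: need cc <= ci <= ca")
  t_dif <- constants$a * (c_a - c_i) / c_a
  t_car <- constants$b * c_c / c_a
  t_pho <- -constants$f * gamma_star_c / c_a
  t_mes <- constants$a_m * (c_i - c_c) / c_a
  structure(list(delta_full = t_dif + t_car + t_pho + t_mes,
                 term_diffusion = t_dif, term_carboxylation = t_car,
                 term_photorespiration = t_pho, term_mesophyll = t_mes),
            class = "discrimination_result")
}

#' GPP-weighted mean discrimination
#'
#' `Delta_w = sum(Delta_t GPP_t) / sum(GPP_t)`: productivity-weighted
#' aggregation of a discrimination series, bounded by the range of the
#' inputs.
#'
#' @param delta discrimination series, per mil.
#' @param gpp_weights productivity weights (any flux unit, only relative
#'   magnitudes matter); must not be all zero.
#' @return weighted mean Delta13C, per mil.
#' @export
gpp_weighted_delta <- function(delta, gpp_weights) {
  if (length(delta) != length(gpp_weights))
    stop("delta and gpp_weights must have equal length")
  keep <- is.finite(delta) & is.finite(gpp_weights)
  delta <- delta[keep]; gpp_weights <- gpp_weights[keep]
  if (sum(gpp_weights) <= 0) stop("undefined weighting: weights sum to zero")
  sum(delta * gpp_weights) / sum(gpp_weights)
}

#' Mesophyll contribution to a discrimination trend per unit CO2
#'
#' Evaluates the mesophyll drawdown term of discrimination,
#' `M(ca) = -(b - a_m) (A/gm) / ca`, at a start and end atmospheric CO2,
#' letting assimilation grow by a prescribed fraction and mesophyll
#' conductance change between the endpoints, and returns the implied
#' contribution `(M_end - M_start) / (ca_end - ca_start)` to the
#' discrimination trend per ppm of CO2 rise. With gm held constant the
#' contribution is positive (discrimination rises with CO2); a modest
#' decline of gm is enough to cancel or reverse it.
#'
#' @param ca_start,ca_end atmospheric CO2 endpoints, umol mol-1.
#' @param A_start assimilation at the start, umol m-2 s-1.
#' @param A_growth_fraction fractional growth of A between endpoints
#'   (e.g. 0.063 for +6.3 percent).
#' @param gm_start,gm_end mesophyll conductance endpoints, mol m-2 s-1.
#' @param constants a [photo_constants()] set.
#' @return contribution to the discrimination trend, per mil per ppm.
#' @export
#' @examples
#' k2017_mesophyll_contribution(330, 377, 9, 0.063, 0.2, 0.2)   # ~ +0.006
#' k2017_mesophyll_contribution(330, 377, 9, 0.063, 0.2, 0.18)  # ~ -0.003
k2017_mesophyll_contribution <- function(ca_start, ca_end, A_start,
                                         A_growth_fraction, gm_start,
                                         gm_end,
                                         constants = photo_constants()) {
  stopifnot(ca_end > ca_start, ca_start > 0, A_start > 0,
            gm_start > 0, gm_end > 0)
  meso <- function(A, gm, ca) -(constants$b - constants$a_m) * (A / gm) / ca
  M1 <- meso(A_start, gm_start, ca_start)
  M2 <- meso(A_start * (1 + A_growth_fraction), gm_end, ca_end)
  (M2 - M1) / (ca_end - ca_start)
}

#' Assimilation growth fraction for a CO2 interval
#'
#' Helper converting a "percent increase of A per doubling of CO2" into
#' the linear fraction over a given CO2 interval:
#' `growth_per_doubling * (ca_end - ca_start) / ca_start`.
#'
#' @param ca_start,ca_end CO2 interval, umol mol-1.
#' @param growth_per_doubling fractional growth of A per CO2 doubling
#'   (default 0.45).
#' @return growth fraction over the interval.
#' @export
#' @examples
#' a_growth_fraction(330, 377)  # ~ 0.064, i.e. ~6.3 percent
a_growth_fraction <- function(ca_start, ca_end, growth_per_doubling = 0.45) {
  growth_per_doubling * (ca_end - ca_start) / ca_start
}

#' Photorespiratory contributions to a discrimination trend
#'
#' Propagates an air-temperature trend through the Arrhenius response of
#' the CO2 compensation point to obtain the implied Gamma* trend
#' (ppm per year), and combines it with the atmospheric CO2 trend through
#' the photorespiratory term `-f Gamma*/ca` of the discrimination model.
#' The Gamma* trend is evaluated pointwise over the supplied leaf
#' temperature range; both the central (mean) value and the half-range
#' are reported.
#'
#' @param dT_per_year air/leaf temperature trend, K per year.
#' @param T_leaf_range leaf temperature evaluation range, degC
#'   (default `c(17, 25)`).
#' @param dCa_per_year atmospheric CO2 trend, ppm per year (default 1.72).
#' @param c_a_ref reference atmospheric CO2, umol mol-1.
#' @param params a [kinetic_params()] set.
#' @param constants a [photo_constants()] set.
#' @param n_points temperature grid size for the range average.
#' @return list with `gamma_star_trend` (ppm per year, central value),
#'   `gamma_star_trend_range` (min/max over the temperature range),
#'   `gamma_star_trend_half_range`, and `photoresp_term_trend` (per mil
#'   per year change of the `-f Gamma*/ca` term combining the Gamma* and
#'   CO2 trends at the central Gamma*).
#' @export
#' @examples
#' photorespiration_trend(0.029)$gamma_star_trend  # ~ 0.053-0.055
photorespiration_trend <- function(dT_per_year, T_leaf_range = c(17, 25),
                                   dCa_per_year = 1.72, c_a_ref = 353,
                                   params = kinetic_params(),
                                   constants = photo_constants(),
                                   n_points = 81) {
  T_K <- seq(T_leaf_range[1], T_leaf_range[2], length.out = n_points) + 273.15
  gs <- gamma_star(T_K, params)
  # analytic derivative of the Arrhenius response: dG/dT = G * Ea / (R T^2)
  dgs_dT <- gs * params$Ea_gamma_star / (8.314 * T_K^2)
  trend_pts <- dgs_dT * dT_per_year
  gs_mid <- mean(gs)
  g_trend <- mean(trend_pts)
  # d/dt [-f G/ca] = -f (G' ca - G ca') / ca^2
  term_trend <- -constants$f *
    (g_trend * c_a_ref - gs_mid * dCa_per_year) / c_a_ref^2
  list(gamma_star_trend = g_trend,
       gamma_star_trend_range = range(trend_pts),
       gamma_star_trend_half_range = diff(range(trend_pts)) / 2,
       photoresp_term_trend = term_trend)
}
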