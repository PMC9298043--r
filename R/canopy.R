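#' Sunlit/shaded light partitioning through the canopy
#'
#' Splits the canopy into `n_layers` equal leaf-area layers and computes,
#' at each layer midpoint of cumulative LAI `L_i`, the sunlit fraction
#' `f_sun,i = exp(-k_b L_i)` with beam extinction
#' `k_b = 0.5 / cos(zenith)`, the direct-beam photon flux on sunlit
#' leaves, and a diffuse exponential profile (extinction 0.7) for shaded
#' leaves. At or beyond 90 degrees zenith the canopy is fully shaded.
#'
#' @param LAI leaf area index, m2 m-2.
#' @param n_layers number of canopy layers (default 10).
#' @param solar_zenith solar zenith angle, degrees.
#' @param PPFD_top above-canopy photon flux, umol m-2 s-1.
#' @param beam_fraction direct-beam fraction of `PPFD_top` (default 0.7).
#' @return data.frame with one row per layer: `L_mid`, `f_sun`,
#'   `PPFD_sun`, `PPFD_shade`.
#' @export
layer_light <- function(LAI, n_layers = 10, solar_zenith = 30,
                        PPFD_top = 1500, beam_fraction = 0.7) {
  if (n_layers < 1) stop("need at least one canopy layer")
  L_mid <- (seq_len(n_layers) - 0.5) * LAI / n_layers
  dark_sun <- solar_zenith >= 90
  k_b <- if (dark_sun) Inf else 0.5 / cos(solar_zenith * pi / 180)
  f_sun <- if (dark_sun) rep(0, n_layers) else exp(-k_b * L_mid)
  k_d <- 0.7
  Q_diff <- PPFD_top * (1 - beam_fraction) * exp(-k_d * L_mid)
  Q_beam <- if (dark_sun) 0 else PPFD_top * beam_fraction
  data.frame(L_mid = L_mid, f_sun = f_sun,
             PPFD_sun = Q_beam + Q_diff, PPFD_shade = Q_diff)
}

#' Canopy upscaling of a leaf-level quantity
#'
#' `X_c = sum_i [f_sun,i X_sun,i + (1 - f_sun,i) X_shade,i] * LAI/n`: each
#' layer's sunlit/shaded mixture weighted by its share of leaf area. Exact
#' for homogeneous canopies (`X_c = X * LAI`).
#'
#' @param X_sun,X_shade per-layer leaf values (equal length).
#' @param f_sun per-layer sunlit fractions.
#' @param LAI leaf area index, m2 m-2.
#' @return canopy total in leaf units times m2 leaf per m2 ground.
#' @export
upscale <- function(X_sun, X_shade, f_sun, LAI) {
  n <- length(f_sun)
  if (length(X_sun) != n || length(X_shade) != n)
    stop("layer arrays must have equal length")
  if (any(f_sun < 0 | f_sun > 1)) stop("f_sun must lie in [0, 1]")
  sum((f_sun * X_sun + (1 - f_sun) * X_shade) * LAI / n)
}

#' Gross primary production from canopy sums
#'
#' `GPP = 0.012 (A_can + R_dc beta_soil)` in kg C m-2 s-1, with canopy
#' assimilation and respiration in mol CO2 m-2 s-1; 0.012 converts mol CO2
#' to kg C. Under the stress convention of [net_assimilation()] this
#' equals 0.012 times the stressed gross rate.
#'
#' @param A_can canopy net assimilation, mol CO2 m-2 s-1.
#' @param R_dc canopy dark respiration, mol CO2 m-2 s-1.
#' @param beta_soil soil water stress factor.
#' @return GPP, kg C m-2 s-1 (use [gpp_to_daily()] for g C m-2 day-1).
#' @export
gpp <- function(A_can, R_dc, beta_soil) {
  0.012 * (A_can + R_dc * beta_soil)
}

#' Convert GPP from kg C m-2 s-1 to g C m-2 day-1
#' @param gpp_kg_s GPP in kg C m-2 s-1.
#' @return GPP in g C m-2 day-1.
#' @export
gpp_to_daily <- function(gpp_kg_s) {
  gpp_kg_s * 1000 * 86400
}

#' Canopy conductance for water and canopy resistance
#'
#' Converts the molar canopy conductance implied by the diffusion relation
#' into a velocity: `G_sw = 1.6 (R T_s / P) A_can / (ca - ci)` in m s-1
#' (the ideal-gas molar volume `R T_s / P` carries the pressure
#' dependence), with `r_c = 1/G_sw` the canopy resistance.
#'
#' @param A_can canopy assimilation, mol m-2 s-1.
#' @param c_a,c_i_eff ambient and effective internal CO2, umol mol-1
#'   (converted internally to mol mol-1).
#' @param T_s surface temperature, K.
#' @param pressure atmospheric pressure, Pa.
#' @return list with `G_sw` (m s-1), `r_c` (s m-1) and the molar `G_sc`
#'   (mol m-2 s-1); `r_c` is `Inf` for zero assimilation.
#' @export
canopy_conductance_water <- function(A_can, c_a, c_i_eff, T_s,
                                     pressure = 101325) {
  if (any(c_a <= c_i_eff)) stop("need ca > effective ci")
  G_sc <- A_can / ((c_a - c_i_eff) * 1e-6)        # mol m-2 s-1
  G_sw <- 1.6 * (8.314 * T_s / pressure) * G_sc   # m s-1
  list(G_sw = G_sw, r_c = ifelse(G_sw > 0, 1 / G_sw, Inf), G_sc = G_sc)
}

#' Surface latent heat flux and evapotranspiration
#'
#' `LE = psi L rho (q_sat(T_s) - q_1) / r_a` in W m-2 from the humidity
#' gradient between the surface and the reference height;
#' `ET = LE / L` converts to a water mass flux.
#'
#' @param psi evaporation-partitioning factor (unitless, default 1).
#' @param rho surface air density, kg m-3.
#' @param r_a aerodynamic resistance, s m-1.
#' @param q_sat_Ts saturated specific humidity at surface temperature,
#'   kg kg-1.
#' @param q_1 specific humidity at reference height, kg kg-1.
#' @param L latent heat of vaporization, J kg-1 (default 2.45e6).
#' @return list with `LE` (W m-2) and `ET` (kg H2O m-2 s-1).
#' @export
latent_heat_flux <- function(psi = 1, rho = 1.2, r_a, q_sat_Ts, q_1,
                             L = 2.45e6) {
  if (any(r_a <= 0)) stop("aerodynamic resistance must be positive")
  LE <- psi * L * rho * (q_sat_Ts - q_1) / r_a
  list(LE = LE, ET = LE / L)
}

#' Canopy transpiration flux
#'
#' `T_r = (1 - f_a) f_v rho (q_sat(T_s) - q_1) / (r_a + r_c)`: the
#' stomatally limited water flux from the dry, vegetated fraction of the
#' surface.
#'
#' @param f_a wet canopy fraction in \[0, 1\].
#' @param f_v vegetated fraction in \[0, 1\].
#' @param rho air density, kg m-3.
#' @param r_a aerodynamic resistance, s m-1.
#' @param r_c canopy resistance, s m-1.
#' @param q_sat_Ts,q_1 specific humidities, kg kg-1.
#' @return T_r, kg H2O m-2 s-1.
#' @export
transpiration <- function(f_a = 0, f_v = 1, rho = 1.2, r_a, r_c,
                          q_sat_Ts, q_1) {
  if (any(f_a < 0 | f_a > 1 | f_v < 0 | f_v > 1))
    stop("surface fractions must lie in [0, 1]")
  if (any(r_a + r_c <= 0)) stop("total resistance must be positive")
  (1 - f_a) * f_v * rho * (q_sat_Ts - q_1) / (r_a + r_c)
}
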