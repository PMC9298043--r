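# Independent oracles and small fixtures shared across tests.

# Brute-force Theil-Sen: explicit double loop over all pairs.
brute_theil_sen <- function(t, y) {
  slopes <- c()
  n <- length(t)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      slopes <- c(slopes, (y[j] - y[i]) / (t[j] - t[i]))
  median(slopes)
}

# Grid-scan oracle for the Leuning closure with residual conductance:
# minimises |closure conductance * (ca - ci) - An(ci)| over a ci grid.
leuning_grid_oracle <- function(met_row, pft, beta_soil, n_grid = 2e4) {
  kin <- kinetic_params("infinite_gm")
  gs <- gamma_star(met_row$T_leaf, kin)
  K <- michaelis_K(met_row$T_leaf, params = kin)
  rates <- kinetic_rates(met_row$T_leaf, pft)
  ci <- seq(gs + 1e-6, met_row$c_a - 1e-6, length.out = n_grid)
  A_C <- carboxylation_rate(rates$Vcmax, ci, gs, K)
  A_J <- light_limited_rate(met_row$PPFD, rates$Jmax, ci, gs, pft)
  An <- net_assimilation(smoothed_min(A_C, A_J, pft$curvature_W),
                         rates$Rd, beta_soil)
  g_cl <- pft$g0 + pft$a1 * An / ((met_row$c_a - gs) * (1 + met_row$D / pft$D0))
  resid <- g_cl * (met_row$c_a - ci) - An
  list(ci = ci[which.min(abs(resid))], step = ci[2] - ci[1])
}

# Constant-conditions met table in the shape produced by generate_met(),
# spanning the given days at a single mid-day timestep per hour.
make_const_met <- function(days = 160:200, hours = 10:14, year = 2000,
                           T_air = 293.15, D = 1, PPFD = 1200, c_a = 380,
                           pressure = 101325, n_years = 1) {
  grid <- expand.grid(hour = hours, doy = days,
                      yr = year + seq_len(n_years) - 1)
  met <- met_state(T_air = T_air, D = D, PPFD = PPFD, c_a = c_a,
                   pressure = pressure,
                   timestamp = as.POSIXct(sprintf("%d-01-01", grid$yr),
                                          tz = "UTC") +
                     ((grid$doy - 1) * 24 + grid$hour) * 3600)
  met$year <- grid$yr
  met$doy <- grid$doy
  met$hour <- grid$hour
  met$zenith <- 30
  met
}

# Saturated soil moisture matrix (beta_soil = 1 everywhere).
saturated_soil <- function(n_steps, profile = soil_profile()) {
  matrix(0.3, n_steps, profile$n_soil)
}
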