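#' Synthetic site scenario
#'
#' Parameters of the seeded weather/CO2 generator used to drive the model
#' without external forcing files: seasonal and diurnal cycles, secular
#' trends, and noise levels. Defaults emulate a northern temperate forest
#' site over a late-20th-century window with atmospheric CO2 rising at
#' 1.72 ppm per year.
#'
#' @param latitude site latitude, degrees (sign sets the hemisphere).
#' @param year_start first simulation year.
#' @param n_years number of years.
#' @param T_mean annual mean air temperature, K.
#' @param T_seasonal_amp seasonal temperature half-amplitude, K.
#' @param T_diurnal_amp diurnal temperature half-amplitude, K.
#' @param T_trend air temperature trend, K per year.
#' @param D_mean mean daytime vapor pressure deficit, kPa.
#' @param D_trend VPD trend, kPa per year.
#' @param rh_noise_sd SD of stochastic relative-humidity anomalies
#'   (fraction).
#' @param co2_start atmospheric CO2 in the first year, umol mol-1.
#' @param co2_trend CO2 ramp, umol mol-1 per year (default 1.72).
#' @param PPFD_max clear-sky solar-noon photon flux, umol m-2 s-1.
#' @param precip_prob daily precipitation occurrence probability.
#' @param pressure atmospheric pressure, Pa.
#' @param theta_mean,theta_seasonal_amp,theta_ar1,theta_noise_sd soil
#'   moisture regime: mean, seasonal half-amplitude, AR(1) coefficient
#'   and innovation SD of the per-layer volumetric water content.
#' @param seed integer random seed; identical scenario + seed gives
#'   bit-identical series.
#' @return object of class `site_scenario`.
#' @export
site_scenario <- function(latitude = 45, year_start = 1979, n_years = 3,
                          T_mean = 283.15, T_seasonal_amp = 10,
                          T_diurnal_amp = 4, T_trend = 0,
                          D_mean = 0.8, D_trend = 0, rh_noise_sd = 0.05,
                          co2_start = 337, co2_trend = 1.72,
                          PPFD_max = 1600, precip_prob = 0.25,
                          pressure = 101325,
                          theta_mean = 0.22, theta_seasonal_amp = 0.04,
                          theta_ar1 = 0.95, theta_noise_sd = 0.005,
                          seed = 1L) {
  sc <- as.list(environment())
  stopifnot(n_years >= 1, co2_start > 0, D_mean >= 0,
            precip_prob >= 0, precip_prob <= 1)
  class(sc) <- "site_scenario"
  sc
}

# day-of-year solar declination (degrees) and zenith at a given hour
solar_geometry <- function(latitude, doy, hour) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365)
  h_angle <- (hour - 12) * 15
  lat_r <- latitude * pi / 180; dec_r <- decl * pi / 180
  cosz <- sin(lat_r) * sin(dec_r) +
    cos(lat_r) * cos(dec_r) * cos(h_angle * pi / 180)
  zen <- acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
  list(cos_zenith = cosz, zenith = zen)
}

#' Generate half-hourly meteorological forcing
#'
#' Produces a seeded half-hourly [met_state()] series from a
#' [site_scenario()]: photon flux from solar geometry, seasonal plus
#' diurnal plus trending air temperature, vapor pressure deficit coupled
#' to temperature through the saturation vapor pressure with stochastic
#' relative-humidity anomalies, a linear CO2 ramp, and daily
#' precipitation occurrence. Deterministic in (scenario, seed).
#'
#' @param scenario a [site_scenario()].
#' @param timestep timestep in hours (default 0.5).
#' @param noise logical; set `FALSE` for the noise- and rain-free
#'   deterministic cycle.
#' @return a [met_state()] data.frame with `timestamp`, plus columns
#'   `year`, `doy`, `hour`, `zenith`.
#' @export
generate_met <- function(scenario = site_scenario(), timestep = 0.5,
                         noise = TRUE) {
  sc <- scenario
  steps_day <- round(24 / timestep)
  days <- 365
  n <- sc$n_years * days * steps_day
  iy <- rep(seq_len(sc$n_years) - 1, each = days * steps_day)
  doy <- rep(rep(seq_len(days), each = steps_day), times = sc$n_years)
  hour <- rep(seq(0, 24 - timestep, by = timestep), times = sc$n_years * days)
  frac_year <- iy + (doy - 1 + hour / 24) / days

  south <- sc$latitude < 0
  season_phase <- 2 * pi * (doy - 196) / 365 * (if (south) -1 else 1)
  diurnal <- -cos(2 * pi * (hour - 2) / 24)

  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(sc$seed)
    rh_anom <- if (noise) stats::rnorm(n, 0, sc$rh_noise_sd) else numeric(n)
    rain_day <- if (noise)
      stats::runif(sc$n_years * days) < sc$precip_prob else
      logical(sc$n_years * days)
    rain_amt <- if (noise) stats::rexp(sc$n_years * days, 1 / 5) else
      numeric(sc$n_years * days)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    list(rh_anom = rh_anom, rain_day = rain_day, rain_amt = rain_amt)
  })

  T_air <- sc$T_mean + sc$T_seasonal_amp * cos(season_phase) +
    sc$T_diurnal_amp * diurnal + sc$T_trend * frac_year

  geom <- solar_geometry(sc$latitude, doy, hour)
  PPFD <- sc$PPFD_max * pmax(geom$cos_zenith, 0)

  # VPD: mean RH implied by D_mean at T_mean, perturbed and trended
  esat <- sat_vapor_pressure(T_air)
  rh_base <- 1 - sc$D_mean / sat_vapor_pressure(sc$T_mean)
  rh <- pmin(pmax(rh_base - rng$rh_anom, 0.05), 1)
  D <- pmax(esat * (1 - rh) + sc$D_trend * frac_year, 0)

  c_a <- sc$co2_start + sc$co2_trend * frac_year

  day_index <- iy * days + doy
  precip <- ifelse(rng$rain_day[day_index] & hour < 1,
                   rng$rain_amt[day_index], 0)

  origin <- as.POSIXct(sprintf("%d-01-01 00:00:00", sc$year_start), tz = "UTC")
  timestamp <- origin + ((iy * days + doy - 1) * 24 + hour) * 3600

  met <- met_state(T_air = T_air, D = D, PPFD = PPFD, c_a = c_a,
                   pressure = sc$pressure, precip = precip,
                   timestamp = timestamp)
  met$year <- sc$year_start + iy
  met$doy <- doy
  met$hour <- hour
  met$zenith <- geom$zenith
  met
}

#' Generate layered soil-moisture series
#'
#' Seasonal sinusoid plus AR(1) noise per soil layer, seeded, clipped to
#' physically admissible water contents.
#'
#' @param scenario a [site_scenario()].
#' @param n_steps number of timesteps.
#' @param n_layers number of soil layers (default 14).
#' @param doy day-of-year per timestep (for the seasonal cycle); defaults
#'   to a uniform wrap over `n_steps`.
#' @return matrix `n_steps x n_layers` of volumetric water content.
#' @export
generate_soil_moisture <- function(scenario = site_scenario(), n_steps,
                                   n_layers = 14, doy = NULL) {
  sc <- scenario
  if (is.null(doy)) doy <- ((seq_len(n_steps) - 1) %% 365) + 1
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(sc$seed + 1000003L)
  season <- sc$theta_mean +
    sc$theta_seasonal_amp * cos(2 * pi * (doy - 60) / 365)
  out <- matrix(0, n_steps, n_layers)
  for (k in seq_len(n_layers)) {
    e <- stats::rnorm(n_steps, 0, sc$theta_noise_sd)
    a <- numeric(n_steps)
    for (i in 2:n_steps) a[i] <- sc$theta_ar1 * a[i - 1] + e[i]
    out[, k] <- pmin(pmax(season + a, 0.02), 0.45)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  out
}

#' Generate a synthetic isotope chronology network with known truth
#'
#' Builds yearly plant delta-13C records by prescribing each site a true
#' discrimination trend and interannual variability, constructing the
#' discrimination series, and inverting the observational conversion
#' (including the post-photosynthetic offset) to plant-material
#' delta-13C against a linearly declining atmospheric delta-13CO2
#' (Suess effect). Returns the records together with the truth table for
#' parameter-recovery tests.
#'
#' @param n_sites number of sites.
#' @param year_start,n_years chronology window.
#' @param slope_mean,slope_sd distribution of true trends, per mil per
#'   year.
#' @param iav_mean mean true IAV (SD of white noise about the trend
#'   line), per mil.
#' @param delta_mean mean discrimination level, per mil.
#' @param f_post_mean,f_post_sd distribution of site post-photosynthetic
#'   offsets, per mil.
#' @param noise_sd measurement noise added to delta-13C, per mil.
#' @param d13c_atm_start,d13c_atm_trend atmospheric delta-13CO2 series
#'   (per mil, per mil per year).
#' @param seed integer seed.
#' @return list with `records` (list of [isotope_record()]; each built
#'   with the standard `f_post` = 2.1 so prescribed site offsets show up
#'   as biases), `truth` (data.frame: site, true slope, true IAV, true
#'   f_post, mean delta), and `atm` (year/d13c_atm table).
#' @export
generate_isotope_network <- function(n_sites = 100, year_start = 1979,
                                     n_years = 34, slope_mean = 0,
                                     slope_sd = 0.02, iav_mean = 0.3,
                                     delta_mean = 18, f_post_mean = 2.1,
                                     f_post_sd = 0, noise_sd = 0,
                                     d13c_atm_start = -7.5,
                                     d13c_atm_trend = -0.025, seed = 1L) {
  stopifnot(n_sites >= 1, n_years >= 3)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed + 2000003L)
  years <- year_start + seq_len(n_years) - 1
  atm <- data.frame(year = years,
                    d13c_atm = d13c_atm_start +
                      d13c_atm_trend * (seq_len(n_years) - 1))
  truth <- data.frame(site = sprintf("SYN%03d", seq_len(n_sites)),
                      slope = stats::rnorm(n_sites, slope_mean, slope_sd),
                      iav = rep(iav_mean, n_sites),
                      f_post = stats::rnorm(n_sites, f_post_mean, f_post_sd),
                      delta_mean = rep(delta_mean, n_sites))
  records <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    delta <- truth$delta_mean[s] +
      truth$slope[s] * (seq_len(n_years) - (n_years + 1) / 2) +
      stats::rnorm(n_years, 0, truth$iav[s]) +
      stats::rnorm(n_years, 0, noise_sd)
    # invert Delta = (da - dcorr)/(1 + dcorr/1000) for dcorr, then add f_post
    dcorr <- (atm$d13c_atm - delta) / (1 + delta / 1000)
    d13c_pm <- dcorr + truth$f_post[s]
    records[[s]] <- isotope_record(truth$site[s], years, d13c_pm,
                                   atm$d13c_atm, tissue = "alpha-cellulose",
                                   f_post = 2.1)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(records = records, truth = truth, atm = atm)
}

#' Generate a synthetic eddy-covariance flux record
#'
#' Half-hourly GPP/LE records with controlled contamination — bad quality
#' flags, sub-threshold vapor pressure deficits, nighttime rows and rain
#' days — so the row count surviving [screen_flux()] is computable in
#' closed form. Deterministic in (scenario, seed).
#'
#' @param scenario a [site_scenario()] (drives the underlying met).
#' @param bad_flag_rate fraction of daytime rows flagged bad.
#' @param low_D_rate fraction of daytime rows with D below 0.01 kPa.
#' @param rain_days integer day indices (1-based from record start) that
#'   receive precipitation; overrides the scenario's stochastic rain.
#' @param timestep timestep in hours.
#' @return data.frame with the columns required by [screen_flux()].
#' @export
generate_flux_record <- function(scenario = site_scenario(),
                                 bad_flag_rate = 0, low_D_rate = 0,
                                 rain_days = integer(0), timestep = 0.5) {
  met <- generate_met(scenario, timestep = timestep, noise = FALSE)
  day_index <- (met$doy - 1) + (met$year - scenario$year_start) * 365 + 1
  met$precip <- ifelse(day_index %in% rain_days & met$hour < 1, 2, 0)

  # simple productivity proxy: GPP proportional to light, LE to VPD-light
  GPP <- 0.02 * met$PPFD
  LE <- pmin(30 + 0.25 * met$PPFD, 500)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(scenario$seed + 3000017L)
  n <- nrow(met)
  daytime <- met$PPFD > 0
  qc <- integer(n)
  idx_day <- which(daytime)
  n_bad <- round(bad_flag_rate * length(idx_day))
  if (n_bad > 0) qc[sample(idx_day, n_bad)] <- 1L
  D <- met$D
  clean_day <- which(daytime & qc == 0)
  n_low <- round(low_D_rate * length(idx_day))
  if (n_low > 0) D[sample(clean_day, min(n_low, length(clean_day)))] <- 0.005
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  data.frame(timestamp = met$timestamp, GPP = GPP, LE = LE, qc_flag = qc,
             PPFD = met$PPFD, D = D, precip = met$precip,
             daytime = daytime)
}
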