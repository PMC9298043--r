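test_that("point runs are deterministic and stationary under periodic forcing", {
  sc <- site_scenario(n_years = 2, T_trend = 0, D_trend = 0, co2_trend = 0,
                      seed = 4)
  met <- generate_met(sc, timestep = 3, noise = FALSE)
  cfg <- run_config(closure = "prentice", scenario = sc, timestep = 3,
                    n_layers = 5)
  soil <- saturated_soil(nrow(met), cfg$soil)
  r1 <- run_point(cfg, met = met, soil_moisture = soil)
  r2 <- run_point(cfg, met = met, soil_moisture = soil)
  expect_identical(r1$timestep, r2$timestep)
  expect_identical(r1$annual, r2$annual)
  # periodic forcing, saturated soil: annual values identical across years
  for (v in c("delta_simple_summer", "delta_full_gppw", "GPP_gC_day",
              "iWUE"))
    expect_equal(r1$annual[[v]][1], r1$annual[[v]][2], tolerance = 1e-10)
})

test_that("seeded stochastic runs are reproducible end to end", {
  cfg <- run_config(closure = "medlyn",
                    scenario = site_scenario(n_years = 1, seed = 6),
                    timestep = 6, n_layers = 3)
  expect_identical(run_point(cfg)$annual, run_point(cfg)$annual)
})

test_that("a rising VPD trend drives discrimination down", {
  sc <- site_scenario(n_years = 6, D_trend = 0.06, co2_trend = 0,
                      rh_noise_sd = 0.01, seed = 10)
  cfg <- run_config(closure = "prentice", scenario = sc, timestep = 3,
                    n_layers = 3)
  res <- run_point(cfg)
  tr <- theil_sen(res$annual$year, res$annual$delta_simple_summer)
  expect_lt(tr$slope, 0)
})

test_that("Medlyn single-layer unstressed run collapses to the closed form", {
  met <- make_const_met(D = 1, PPFD = 1200, c_a = 380)
  pft <- pft_params(g1 = 4, LAI = 2)
  cfg <- run_config(closure = "medlyn", pft = pft, n_layers = 1,
                    scenario = site_scenario(n_years = 1))
  res <- run_point(cfg, met = met, soil_moisture = saturated_soil(nrow(met)))
  expected <- 4.4 + (27 - 4.4) * 4 / (4 + sqrt(1))
  expect_equal(res$annual$delta_simple_summer, expected, tolerance = 1e-10)
  expect_equal(res$annual$delta_simple_gppw, expected, tolerance = 1e-10)
  expect_equal(res$annual$ci_over_ca, 4 / 5, tolerance = 1e-10)
})

test_that("summer and GPP-weighted aggregations share one timestep series", {
  sc <- site_scenario(n_years = 1, seed = 12)
  cfg_s <- run_config(closure = "prentice", scenario = sc, timestep = 6,
                      n_layers = 3, aggregation = "summer")
  cfg_w <- run_config(closure = "prentice", scenario = sc, timestep = 6,
                      n_layers = 3, aggregation = "gpp_weighted")
  rs <- run_point(cfg_s); rw <- run_point(cfg_w)
  expect_identical(rs$timestep, rw$timestep)
  expect_identical(rs$annual, rw$annual)
})

test_that("within-canopy Vcmax decay reduces productivity, not leaf ci", {
  met <- make_const_met(D = 1, PPFD = 1200, c_a = 380)
  soil <- saturated_soil(nrow(met))
  base <- run_config(closure = "medlyn", n_layers = 4,
                     scenario = site_scenario(n_years = 1))
  dec <- run_config(closure = "medlyn", n_layers = 4,
                    scenario = site_scenario(n_years = 1),
                    vcmax_decay = 0.2)
  r0 <- run_point(base, met = met, soil_moisture = soil)
  r1 <- run_point(dec, met = met, soil_moisture = soil)
  expect_lt(r1$annual$GPP_gC_day, r0$annual$GPP_gC_day)
  # the closure's ci is capacity-independent, so discrimination is unchanged
  expect_equal(r1$annual$delta_simple_summer, r0$annual$delta_simple_summer,
               tolerance = 1e-10)
  expect_error(run_config(vcmax_decay = -0.1))
})

test_that("comparison report recovers a constructed bias", {
  net <- generate_isotope_network(n_sites = 6, iav_mean = 0.3,
                                  delta_mean = 18, seed = 15)
  years <- net$atm$year
  # prediction = observation + 2.4 per mil for one site
  obs <- record_delta(net$records[[1]])
  pred_same <- obs; names(pred_same)[2] <- "delta13C"
  rep0 <- compare_obs(pred_same, net$records[1])
  expect_equal(rep0$bias, 0, tolerance = 1e-10)
  expect_equal(rep0$r, 1, tolerance = 1e-10)
  pred_bias <- data.frame(year = years, delta13C = obs$delta13C + 2.4)
  rep1 <- compare_obs(pred_bias, net$records[1])
  expect_equal(rep1$bias, 2.4, tolerance = 1e-10)
  # flat prediction is flagged as less variable than the observations
  pred_flat <- data.frame(year = years,
                          delta13C = mean(obs$delta13C) +
                            0.001 * seq_along(years))
  rep2 <- compare_obs(pred_flat, net$records[1])
  expect_true(rep2$iav_deficit)
  expect_error(compare_obs(data.frame(year = 1900:1910, delta13C = 18),
                           net$records[1]), "empty comparison")
})
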