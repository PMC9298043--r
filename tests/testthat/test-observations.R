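test_that("discrimination from plant and atmospheric delta-13C", {
  expect_equal(delta_from_d13c(-8, -24, 2.1), 18.1 / (1 - 26.1 / 1000),
               tolerance = 1e-12)
  expect_equal(delta_from_d13c(-8, -28, 0), 20 / 0.972, tolerance = 1e-12)
  # plant matter isotopically identical to source air: no discrimination
  expect_equal(delta_from_d13c(-8, -8, 0), 0)
  # strictly decreasing in plant delta, increasing in f_post
  dp <- seq(-30, -20, by = 1)
  expect_true(all(diff(delta_from_d13c(-8, dp, 2.1)) < 0))
  fp <- seq(0, 4, by = 0.5)
  expect_true(all(diff(delta_from_d13c(-8, -26, fp)) > 0))
  expect_error(delta_from_d13c(-8, -1000, 0), "singular")
})

test_that("apparent post-photosynthetic fractionation from paired tissues", {
  expect_equal(apparent_fpost(-28, -24), 4)
  # bulk wood gets the alpha-cellulose correction
  expect_equal(apparent_fpost(-28, -25, wood_is_bulk = TRUE), 3 + 1.1)
  expect_equal(apparent_fpost(c(-28, -27), c(-24, -25)), c(4, 2))
})

test_that("per-network f_post summaries match the shipped site table", {
  s <- fpost_site_estimates(summarise = TRUE)
  am <- s[s$network == "AmeriFlux", ]
  ce <- s[s$network == "CarboEuropeFlux", ]
  expect_equal(am$n, 15)
  expect_equal(am$mean_fpost, 4.05, tolerance = 0.01)
  expect_equal(am$sd_fpost, 1.14, tolerance = 0.01)
  expect_equal(ce$n, 9)
  expect_equal(ce$mean_fpost, 2.2, tolerance = 0.05)
})

test_that("chronology selection enforces the in-window coverage rule", {
  mk <- function(site, years) {
    isotope_record(site, years, rep(-25, length(years)), -8)
  }
  r30 <- mk("keep30", 1980:2009)       # 30 in-window years
  r25 <- mk("keep25", 1985:2009)       # exactly 25
  r24 <- mk("drop24", 1986:2009)       # 24: below threshold
  rout <- mk("dropout", 1940:1978)     # outside the window
  kept <- select_chronologies(list(r30, r24, r25, rout))
  expect_equal(vapply(kept, `[[`, "", "site"), c("keep30", "keep25"))
  # missing values inside the window do not count
  ym <- 1980:2009
  dm <- rep(-25, 30); dm[1:6] <- NA
  rmiss <- isotope_record("miss", ym, dm, -8)
  expect_length(select_chronologies(list(rmiss)), 0)
  # synthetic set: 6 of 10 pass
  set <- c(lapply(1:6, function(i) mk(paste0("p", i), 1980:2009)),
           lapply(1:4, function(i) mk(paste0("f", i), 2000:2009)))
  expect_length(select_chronologies(set), 6)
})

test_that("flux screening applies each rule and the 24-h rain exclusion", {
  # 4-day hourly fixture, rain on day 2 -> days 2 and 3 removed
  ts <- seq(as.POSIXct("2005-06-01 00:00", tz = "UTC"), by = 3600,
            length.out = 4 * 24)
  hour <- as.integer(format(ts, "%H"))
  day <- as.integer(format(ts, "%d"))
  flux <- data.frame(timestamp = ts, GPP = 10, LE = 100, qc_flag = 0,
                     PPFD = ifelse(hour >= 6 & hour <= 18, 800, 0),
                     D = 1, precip = ifelse(day == 2 & hour == 10, 3, 0))
  res <- screen_flux(flux)
  days_kept <- unique(as.integer(format(res$screened$timestamp, "%d")))
  expect_equal(days_kept, c(1, 4))
  # daytime-only retained
  expect_true(all(res$screened$PPFD > 0))
  # low-D and bad-flag rows are removed
  flux2 <- flux
  flux2$D[10:12] <- 0.005
  flux2$qc_flag[30] <- 1
  res2 <- screen_flux(flux2)
  expect_false(any(res2$screened$D < 0.01))
  expect_equal(unname(res2$n_removed["bad_flag"]), 1)
  # retained count equals the conjunction of all rules applied row-by-row
  all_days <- as.Date(flux2$timestamp)
  rain_days <- unique(all_days[flux2$precip > 0])
  keep <- flux2$qc_flag == 0 & flux2$D >= 0.01 & flux2$PPFD > 0 &
    !(all_days %in% c(rain_days, rain_days + 1))
  expect_equal(res2$n_retained, sum(keep))
  # unit conversions on survivors
  expect_equal(res$screened$GPP_gC_day[1], 10 * 1e-6 * 12 * 86400)
  expect_equal(res$screened$ET_kg_day[1], 100 / 2.45e6 * 86400)
  # growing-season means (June fixture)
  expect_equal(res$season_means$year, 2005)
  expect_error(screen_flux(flux[, -2]), "missing columns")
})

test_that("screening everything away is flagged, not an error", {
  ts <- seq(as.POSIXct("2005-06-01 00:00", tz = "UTC"), by = 3600,
            length.out = 24)
  flux <- data.frame(timestamp = ts, GPP = 10, LE = 100, qc_flag = 1,
                     PPFD = 800, D = 1, precip = 0)
  res <- screen_flux(flux)
  expect_equal(res$n_retained, 0)
  expect_true(attr(res$season_means, "empty_season"))
})

test_that("isotope record files round-trip through the readers", {
  tmp <- tempfile(fileext = ".csv"); atm <- tempfile(fileext = ".csv")
  write.csv(data.frame(site = "S1", species = "PISY",
                       tissue = "alpha-cellulose", year = 2000:2004,
                       d13c = c(-24.1, -24.3, -24, -24.6, -24.2)),
            tmp, row.names = FALSE)
  write.csv(data.frame(year = 2000:2004, d13c_atm = seq(-8, -8.1, -0.025)),
            atm, row.names = FALSE)
  recs <- read_isotope_records(tmp, atm)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$years, 2000:2004)
  d <- record_delta(recs[[1]])
  expect_equal(d$delta13C[1], delta_from_d13c(-8, -24.1, 2.1))
})
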