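test_that("Theil-Sen slope is the pairwise-slope median", {
  expect_equal(theil_sen(1:10, rep(5, 10))$slope, 0)
  # pairwise slopes {1, 2, 3}, median 2
  expect_equal(theil_sen(0:2, c(0, 1, 4))$slope, 2)
  # exact line recovered exactly
  tr <- theil_sen(1:20, 3 - 0.25 * (1:20))
  expect_equal(tr$slope, -0.25, tolerance = 1e-12)
  expect_equal(tr$iav, 0, tolerance = 1e-12)
  expect_error(theil_sen(1:2, 1:2), "insufficient")
  expect_error(theil_sen(c(1, 1, 2), 1:3), "distinct")
})

test_that("Theil-Sen matches the brute-force oracle on random series", {
  set.seed(19)
  for (n in c(5, 17, 60, 200)) {
    t <- sort(sample(1:500, n))
    y <- 0.1 * t + rnorm(n, 0, 3)
    expect_equal(theil_sen(t, y)$slope, brute_theil_sen(t, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Kendall significance flags clear trends and not noise", {
  set.seed(5)
  y_trend <- 0.1 * (1:40) + rnorm(40, 0, 0.3)
  expect_lt(theil_sen(1:40, y_trend)$p_value, 0.05)
  y_flat <- rnorm(40)
  expect_gt(theil_sen(1:40, y_flat)$p_value, 0.05)
})

test_that("IAV is the sample SD of residuals about the robust line", {
  # exact line: zero variability
  expect_equal(iav(1:10, 2 + 0.5 * (1:10)), 0, tolerance = 1e-12)
  # shift invariance
  set.seed(3)
  y <- 0.2 * (1:15) + rnorm(15)
  expect_equal(iav(1:15, y), iav(1:15, y + 100), tolerance = 1e-10)
  # frozen small case checked against an enumeration oracle
  t4 <- 1:4; y4 <- c(1, 5, 5, 9)
  sl <- brute_theil_sen(t4, y4)
  ic <- median(y4) - sl * median(t4)
  expect_equal(iav(t4, y4), sd(y4 - (ic + sl * t4)), tolerance = 1e-12)
})

test_that("Taylor statistics satisfy the law-of-cosines identity", {
  obs <- c(1, 3, 2, 5, 4, 6)
  expect_equal(taylor_stats(obs, obs)[c("r", "norm_sd", "crmse")],
               list(r = 1, norm_sd = 1, crmse = 0), tolerance = 1e-12)
  expect_equal(taylor_stats(obs, -obs)$r, -1)
  set.seed(13)
  for (k in 1:20) {
    o <- rnorm(30); p <- 0.5 * o + rnorm(30)
    st <- taylor_stats(o, p)
    expect_equal(st$crmse^2,
                 st$sd_pred^2 + st$sd_obs^2 -
                   2 * st$sd_pred * st$sd_obs * st$r,
                 tolerance = 1e-12)
  }
  expect_error(taylor_stats(rep(1, 5), 1:5), "zero variance")
})

test_that("binned scores mask sparse cells and use half-open bins", {
  clim <- data.frame(T_air = c(2, 3))
  g <- binned_score(c(0.1, 0.3), clim, list(T_air = c(0, 5, 10)),
                    min_count = 0)
  expect_equal(g$mean, 0.2)
  expect_equal(g$count, 2)
  # exactly 20 points is NOT strictly more than 20: masked
  clim20 <- data.frame(T_air = rep(2, 20))
  g20 <- binned_score(rep(1, 20), clim20, list(T_air = c(0, 5)),
                      min_count = 20)
  expect_true(is.na(g20$mean))
  expect_equal(g20$count, 20)
  # half-open [lo, hi): edge point goes to the upper cell
  ge <- binned_score(c(1, 2), data.frame(T_air = c(4.9, 5)),
                     list(T_air = c(0, 5, 10)), min_count = 0)
  expect_equal(ge$T_air_lo, c(0, 5))
  expect_equal(ge$mean, c(1, 2))
  # mass conservation over a 2-axis grid
  set.seed(8)
  clim2 <- data.frame(T_air = runif(300, 0, 20), D = runif(300, 0, 2))
  g2 <- binned_score(rnorm(300), clim2,
                     list(T_air = seq(0, 20, 5), D = seq(0, 2, 0.4)),
                     min_count = 0)
  expect_equal(sum(g2$count), 300)
})

test_that("variance partitioning recovers known structure", {
  set.seed(21)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  # pure identity: all variance to the first driver
  vp <- variance_partition(x1, data.frame(CO2 = x1, T_air = x2, D = x3))
  expect_equal(unname(vp$variance_pct["CO2"]), 100, tolerance = 1)
  expect_lt(max(vp$variance_pct[c("T_air", "D")]), 1)
  # orthogonal standardized drivers: share_j ~ beta_j^2
  y <- 0.9 * scale(x1)[, 1] + 0.3 * scale(x2)[, 1] + rnorm(n, 0, 0.3)
  vp2 <- variance_partition(y, data.frame(CO2 = x1, T_air = x2, D = x3))
  expect_lt(abs(unname(vp2$coefficients["CO2"]) * sd(y) - 0.9), 0.05)
  expect_lt(abs(unname(vp2$coefficients["T_air"]) * sd(y) - 0.3), 0.05)
  # shares sum to R^2 in percent
  expect_equal(sum(vp2$variance_pct), vp2$r_squared * 100,
               tolerance = 1e-8)
  expect_error(variance_partition(1:3, data.frame(a = 1:3, b = 1:3, c = 1:3)),
               "more observations")
})
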