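test_that("Jacobs closure interpolates between ca and the compensation point", {
  expect_equal(ci_jacobs(400, 42.75, 0.8, 0, 0.09),
               0.8 * 357.25 + 42.75, tolerance = 1e-12)
  expect_equal(ci_jacobs(400, 42.75, 0.8, 0.09, 0.09), 42.75)
  expect_equal(ci_jacobs(400, 42.75, 1, 0, 0.09), 400)
  # clipped at the compensation point beyond the critical deficit
  expect_equal(ci_jacobs(400, 42.75, 0.8, 0.2, 0.09), 42.75)
  expect_error(ci_jacobs(400, 42.75, 0.8, 0.01, 0), "dq_crit")
})

test_that("Medlyn closure follows g1/(g1 + sqrt(D))", {
  expect_equal(ci_medlyn(400, 4, 0), 400)
  expect_equal(ci_medlyn(400, 4, 1), 320)
  # symmetry point D = g1^2 halves ci
  expect_equal(ci_medlyn(400, 4, 16), 200)
  expect_error(ci_medlyn(400, -1, 1), "g1")
})

test_that("Leuning g0 = 0 closed form and feasibility boundary", {
  expect_equal(ci_leuning(400, 42.75, 9, 1.5, 1.5),
               400 - 357.25 * 2 / 9, tolerance = 1e-12)
  # a1 at the feasibility boundary pins ci at the compensation point
  expect_equal(as.numeric(ci_leuning(400, 42.75, 2, 1.5, 1.5)), 42.75)
  deg <- ci_leuning(400, 42.75, 1.5, 1.5, 1.5)
  expect_true(attr(deg, "degenerate"))
  expect_error(ci_leuning(400, 42.75, 9, 1, 0), "D0")
})

test_that("Prentice least-cost closure reproduces the closed-form ratio", {
  # beta = 146, Gamma* = 42.75 ppm (4.24 Pa at 99.1 kPa), K = 704 ppm,
  # D = 1 kPa -> ci/ca ~ 0.75
  ci <- ci_prentice(400, 42.75, 704, 1, 146, 99100)
  expect_equal(ci / 400, 0.752, tolerance = 2e-3)
  expect_equal(ci_prentice(400, 42.75, 704, 0, 146, 99100), 400)
  expect_equal(ci_prentice(400, 42.75, 704, 1e9, 146, 99100), 42.75,
               tolerance = 1e-2)
  expect_error(ci_prentice(400, 42.75, 704, 1, -5), "beta_cost")
})

test_that("chloroplastic closure reduces to and departs from the ci form", {
  kin <- kinetic_params("finite_gm")
  gs <- gamma_star(298.15, kin); Kc <- michaelis_K(298.15, params = kin)
  expect_equal(cc_prentice(400, gs, Kc, 1, 146, gsc_over_gm = 0),
               ci_prentice(400, gs, Kc, 1, 146), tolerance = 1e-12)
  expect_equal(cc_prentice(400, gs, Kc, 0, 146), 400)
  # strictly decreasing in the conductance ratio at D > 0
  r <- c(0, 0.25, 0.5, 1)
  cc <- vapply(r, function(x) cc_prentice(400, gs, Kc, 1, 146,
                                          gsc_over_gm = x), numeric(1))
  expect_true(all(diff(cc) < 0))
})

test_that("diffusion relation and iWUE are consistent", {
  expect_equal(stomatal_conductance(8, 400, 280), 8 / 120, tolerance = 1e-12)
  expect_equal(stomatal_conductance(0, 400, 400), 0)
  expect_equal(stomatal_conductance(16, 400, 280),
               2 * stomatal_conductance(8, 400, 280))
  expect_error(stomatal_conductance(5, 400, 400), "degenerate")
  expect_equal(iwue(400, 280), 75)
  expect_equal(iwue(400, 400), 0)
  # iWUE scales with ca at fixed ci/ca
  expect_equal(iwue(800, 560), 2 * iwue(400, 280))
})

test_that("every closure keeps ci within bounds and responds negatively to D", {
  set.seed(11)
  kin <- kinetic_params()
  for (k in 1:40) {
    ca <- runif(1, 300, 500)
    T_leaf <- runif(1, 283, 308)
    gs <- gamma_star(T_leaf, kin)
    K <- michaelis_K(T_leaf, params = kin)
    D <- runif(1, 0.05, 3)
    vals <- c(
      jacobs = ci_jacobs(ca, gs, runif(1, 0.6, 0.95),
                         runif(1, 0, 0.05), 0.09),
      medlyn = ci_medlyn(ca, runif(1, 2, 6), D),
      leuning = as.numeric(ci_leuning(ca, gs, runif(1, 5, 12), D, 1.5)),
      prentice = ci_prentice(ca, gs, K, D, runif(1, 50, 300))
    )
    expect_true(all(vals <= ca + 1e-9))
    expect_true(all(vals[c("jacobs", "leuning", "prentice")] >= gs - 1e-9))
    expect_gte(vals["medlyn"], 0)
    # dci/dD <= 0 for the humidity-responsive closures
    dD <- 0.1
    expect_lte(ci_medlyn(ca, 4, D + dD), ci_medlyn(ca, 4, D))
    expect_lte(as.numeric(ci_leuning(ca, gs, 9, D + dD, 1.5)),
               as.numeric(ci_leuning(ca, gs, 9, D, 1.5)))
    expect_lte(ci_prentice(ca, gs, K, D + dD, 146),
               ci_prentice(ca, gs, K, D, 146))
  }
})

test_that("leaf solver satisfies the governing relations simultaneously", {
  set.seed(23)
  for (closure in c("jacobs", "medlyn", "prentice", "prentice-cc")) {
    met <- met_state(T_air = runif(5, 285, 305), D = runif(5, 0.2, 2.5),
                     PPFD = runif(5, 200, 1800), c_a = runif(5, 340, 420))
    pft <- pft_params()
    beta <- runif(5, 0.3, 1)
    leaf <- solve_leaf(met, pft, beta, closure)
    kinv <- kinetic_params(if (closure == "prentice-cc") "finite_gm"
                           else "infinite_gm")
    gs <- gamma_star(met$T_leaf, kinv)
    K <- michaelis_K(met$T_leaf, params = kinv)
    rates <- kinetic_rates(met$T_leaf, pft)
    cs <- if (closure == "prentice-cc") leaf$c_c else leaf$c_i
    # Farquhar rates at the returned substrate CO2
    expect_equal(leaf$A_C, carboxylation_rate(rates$Vcmax, cs, gs, K),
                 tolerance = 1e-8)
    expect_equal(leaf$A_n,
                 net_assimilation(smoothed_min(leaf$A_C, leaf$A_J,
                                               pft$curvature_W),
                                  rates$Rd, beta),
                 tolerance = 1e-8)
    # diffusion relation where assimilation is positive
    pos <- leaf$A_n > 0
    expect_equal(leaf$g_sc[pos],
                 (leaf$A_n / (met$c_a - leaf$c_i))[pos], tolerance = 1e-8)
    # ordering cc <= ci <= ca
    expect_true(all(leaf$c_c <= leaf$c_i + 1e-9))
    expect_true(all(leaf$c_i <= met$c_a + 1e-9))
  }
})

test_that("Medlyn solver ci is the exact closed form and dark states are forced", {
  met <- met_state(T_air = 295, D = 1.21, PPFD = c(1000, 0), c_a = 400)
  pft <- pft_params(g1 = 4)
  leaf <- solve_leaf(met, pft, 0.8, "medlyn")
  expect_equal(leaf$c_i[1], 400 * 4 / (4 + sqrt(1.21)), tolerance = 1e-12)
  # dark: An = -Rd * beta, nighttime conductance
  expect_equal(leaf$A_n[2], -leaf$Rd[2] * 0.8, tolerance = 1e-12)
  expect_equal(leaf$g_sc[2], pft$g_night)
  expect_equal(leaf$c_i[2], 400)
})

test_that("Leuning with residual conductance matches a grid-scan oracle", {
  set.seed(31)
  pft <- pft_params(g0 = 0.02)
  for (k in 1:12) {
    met <- met_state(T_air = runif(1, 288, 303), D = runif(1, 0.3, 2),
                     PPFD = runif(1, 300, 1600), c_a = runif(1, 350, 420))
    beta <- runif(1, 0.5, 1)
    leaf <- solve_leaf(met, pft, beta, "leuning")
    oracle <- leuning_grid_oracle(met[1, ], pft, beta)
    expect_equal(leaf$c_i, oracle$ci, tolerance = 2 * oracle$step / oracle$ci)
  }
})
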