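p <- il27_parameters()

test_that("net growth inverts exponential series exactly", {
  expect_equal(net_growth_from_series(c(11, 14, 17, 20),
                                      3 * exp(0.2 * c(11, 14, 17, 20))),
               0.2)
  expect_equal(net_growth_from_series(c(0, 1, 2), c(1, 2, 4)), log(2))
  expect_identical(net_growth_from_series(c(1, 3, 9), c(5, 5, 5)), 0)
  expect_error(net_growth_from_series(1, 5), "two observations")
  expect_error(net_growth_from_series(c(1, 2), c(1, 0)), "positive")
  expect_error(net_growth_from_series(c(2, 1), c(1, 1)), "increasing")
})

test_that("half-life inversion is consistent with forward decay", {
  expect_equal(rate_from_halflife(log(2)), 1)
  expect_equal(rate_from_halflife(2), log(2) / 2)
  expect_error(rate_from_halflife(0), "positive")
  # forward-simulate the decay at the returned rate over one half-life
  d <- rate_from_halflife(3.7)
  out <- deSolve::ode(y = 10, times = c(0, 3.7),
                      func = function(t, y, pp) list(-d * y), parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(rel_err(out[2, 2], 5), 1e-8)
})

test_that("production estimator is the exact inverse of its forward ODE", {
  a <- 3e-5; S <- 2e6; d <- 9
  # steady state: returns d*u/S
  u_ss <- a * S / d
  expect_equal(production_from_two_points(u_ss, u_ss, 1, 5, S, d), a,
               tolerance = 1e-12)
  # independent numerical forward simulation, then inversion
  out <- deSolve::ode(y = 2, times = c(1, 5),
                      func = function(t, y, pp) list(a * S - d * y),
                      parms = NULL, rtol = 1e-12, atol = 1e-14)
  expect_lt(rel_err(production_from_two_points(2, out[2, 2], 1, 5, S, d), a),
            1e-8)
  expect_error(production_from_two_points(1, 2, 1, 5, 0, d), "positive")
  expect_error(production_from_two_points(1, 2, 5, 1, S, d), "t2")
})

test_that("enhancement estimator recovers lam2 including degenerate cases", {
  lam1 <- 2e-5; lam2 <- 2.5e-4; K <- 2000; d <- 9; E <- 4e6; I27 <- 1500
  src <- (lam1 + lam2 * I27 / (K + I27)) * E
  u2 <- lin_closed(3, src, d, 4)
  expect_lt(rel_err(enhanced_production(3, u2, 1, 5, E, I27, K, lam1, d),
                    lam2), 1e-10)
  # lam2 = 0 data returns 0
  u2b <- lin_closed(3, lam1 * E, d, 4)
  expect_lt(abs(enhanced_production(3, u2b, 1, 5, E, I27, K, lam1, d)),
            1e-10 * lam2)
  # saturated limit: reduces to total production lam1 + lam2
  u2c <- lin_closed(3, (lam1 + lam2) * E, d, 4)
  expect_lt(rel_err(enhanced_production(3, u2c, 1, 5, E, 1e12, K, lam1, d),
                    lam2), 1e-6)
  expect_error(enhanced_production(3, 5, 1, 5, E, 0, K, lam1, d),
               "unidentifiable")
})

test_that("activation and effective-death estimators invert the CTL ODE", {
  lamE <- 5.8e5; K_T <- 1e7; d_E <- 1.4; Tb <- 2e8; E1 <- 8e6
  A <- lamE * Tb / (K_T + Tb)
  # steady state satisfies the fixed-point identity
  E_ss <- A / d_E
  expect_equal(activation_rate(E_ss, E_ss, 1, 5, Tb, K_T, d_E), lamE,
               tolerance = 1e-12)
  # round trip through an independent forward integration
  out <- deSolve::ode(y = E1, times = c(1, 5),
                      func = function(t, y, pp) list(A - d_E * y),
                      parms = NULL, rtol = 1e-12, atol = 1e-10)
  expect_lt(rel_err(activation_rate(E1, out[2, 2], 1, 5, Tb, K_T, d_E),
                    lamE), 1e-8)
  # two-arm fixture: the IL-27 arm's reduced death rate is recovered and
  # yields the survival half-saturation
  K_E1 <- 600; I27b <- 1800
  d_red <- d_E / (1 + I27b / K_E1)
  E5_red <- lin_closed(E1, A, d_red, 4)
  d_hat <- effective_death_rate(E1, E5_red, 1, 5, A)
  expect_lt(rel_err(d_hat, d_red), 1e-9)
  expect_lt(rel_err(I27b / (d_E / d_hat - 1), K_E1), 1e-8)
})

test_that("kill-rate estimator inverts saturating killing", {
  g <- 0.34; eta <- 1.0; K <- 25; u <- 12
  # no killing observed means eta = 0
  expect_equal(killing_rate(1e8, 1e8 * exp(g * 4), 1, 5, g, u, K), 0,
               tolerance = 1e-12)
  # round trip
  T2 <- 1e8 * exp((g - eta * u / (K + u)) * 4)
  expect_lt(rel_err(killing_rate(1e8, T2, 1, 5, g, u, K), eta), 1e-10)
  # saturated limit: eta equals the growth deficit
  T2s <- 1e8 * exp((g - 0.25) * 4)
  expect_lt(rel_err(killing_rate(1e8, T2s, 1, 5, g, 1e12, K), 0.25), 1e-6)
  expect_error(killing_rate(1e8, 1e8, 1, 5, g, 0, K), "positive")
})

test_that("the full cascade recovers every parameter from noiseless data", {
  obs <- generate_observations(p, observation_design(cv = 0))
  est <- estimate_all(obs, fixed = fixed_constants(p),
                      kappa = p$K_E2 / p$K_E1)
  truth <- truth_from_params(p)
  expect_identical(length(est$unestimable), 0L)
  expect_lt(max(rel_err(est$estimates[names(truth)], truth)), 1e-8)
})

test_that("missing knockout arms disable only the dependent estimates", {
  des <- observation_design(cv = 0,
                            genotypes = c("P1CTL", "P1CTL_IL27"))
  est <- estimate_all(generate_observations(p, des),
                      fixed = fixed_constants(p), kappa = p$K_E2 / p$K_E1)
  expect_true(all(is.na(est$estimates[c("eta1", "eta2", "lamE",
                                        "K_E1", "K_E2")])))
  expect_true(all(c("eta1", "eta2", "lamE", "K_E1") %in%
                  names(est$unestimable)))
  # upstream estimates unchanged relative to the complete design
  full <- estimate_all(generate_observations(p, observation_design(cv = 0)),
                       fixed = fixed_constants(p), kappa = p$K_E2 / p$K_E1)
  up <- c("g", "lamT", "d_T", "mu1", "lam1", "lam2", "lamG")
  expect_equal(est$estimates[up], full$estimates[up], tolerance = 1e-12)
})

test_that("geometric averaging is available and consistent at steady state", {
  obs <- generate_observations(p, observation_design(cv = 0))
  est <- estimate_all(obs, fixed = fixed_constants(p),
                      kappa = p$K_E2 / p$K_E1, averaging = "geometric")
  # growth-rate pieces do not involve averages and stay exact
  expect_lt(rel_err(est$estimates[["g"]], p$lamT - p$d_T), 1e-10)
  expect_true(all(is.finite(est$estimates)))
})
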