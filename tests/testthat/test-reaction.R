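p <- il27_parameters()

test_that("no cells means no fluxes anywhere in the network", {
  u0 <- c(I27 = 0, I10 = 0, E = 0, G = 0, T = 0)
  expect_identical(unname(reaction_rates(u0, p)), rep(0, 5))
})

test_that("tumor-only state drives exactly the tumor-sourced terms", {
  TT <- 5e7
  r <- reaction_rates(c(I27 = 0, I10 = 0, E = 0, G = 0, T = TT), p)
  expect_equal(r[["I27"]], p$mu1 * TT)
  expect_equal(r[["E"]], p$lamE * TT / (p$K_T + TT))
  expect_identical(r[["I10"]], 0)
  expect_identical(r[["G"]], 0)
  expect_equal(r[["T"]], p$lamT * TT * (1 - TT / p$T_max) - p$d_T * TT)
})

test_that("IL-10 enhancement contributes exactly half its maximum at the
           half-saturation point", {
  E <- 3e6; I10 <- 7
  u <- c(I27 = p$K_I27_10, I10 = I10, E = E, G = 0, T = 0)
  r <- reaction_rates(u, p)
  # independent arithmetic evaluation of the stated formula
  expect_equal(r[["I10"]], p$lam1 * E + p$lam2 * E / 2 - p$d_I10 * I10,
               tolerance = 1e-14)
})

test_that("rates are linear in the injection source", {
  set.seed(7)
  for (i in 1:20) {
    u <- c(I27 = runif(1, 0, 5e3), I10 = runif(1, 0, 50),
           E = runif(1, 0, 1e7), G = runif(1, 0, 1e3),
           T = runif(1, 0, 9e8))
    f1 <- runif(1, 0, 1e5); f2 <- runif(1, 0, 1e5)
    lhs <- reaction_rates(u, p, f1 + f2) - reaction_rates(u, p, f2)
    rhs <- reaction_rates(u, p, f1) - reaction_rates(u, p, 0)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("IL-27 saturations are monotone with the stated limits", {
  E <- 2e6
  i27 <- c(0, 10^(0:8))
  gprod <- sapply(i27, function(x)
    reaction_rates(c(I27 = x, I10 = 0, E = E, G = 0, T = 0), p)[["G"]])
  expect_true(all(diff(gprod) < 0))           # IFN-gamma production inhibited
  expect_lt(gprod[length(gprod)], 1e-3 * gprod[1])  # -> 0 as I27 -> Inf
  i10prod <- sapply(i27, function(x)
    reaction_rates(c(I27 = x, I10 = 0, E = E, G = 0, T = 0), p)[["I10"]])
  expect_true(all(diff(i10prod) > 0))         # enhancement saturates upward
  expect_lt(abs(i10prod[length(i10prod)] - (p$lam1 + p$lam2) * E),
            1e-3 * p$lam2 * E)                # -> (lam1 + lam2) E
})

test_that("survival cytokines reduce the CTL death term monotonically", {
  E <- 1e6
  dE_at <- function(i27, i10)
    reaction_rates(c(I27 = i27, I10 = i10, E = E, G = 0, T = 0), p)[["E"]]
  expect_true(all(diff(sapply(10^(0:6), dE_at, i10 = 0)) > 0))
  expect_true(all(diff(sapply(10^(0:6), function(x) dE_at(0, x))) > 0))
})

test_that("killing terms only remove tumor cells", {
  set.seed(11)
  for (i in 1:20) {
    u <- c(I27 = runif(1, 0, 5e3), I10 = runif(1, 0, 100),
           E = runif(1, 0, 1e7), G = runif(1, 0, 1e3),
           T = runif(1, 0, 9e8))
    bound <- p$lamT * u[["T"]] * (1 - u[["T"]] / p$T_max) - p$d_T * u[["T"]]
    expect_lte(reaction_rates(u, p)[["T"]], bound + 1e-9 * abs(bound))
  }
})

test_that("invalid states are rejected", {
  expect_error(reaction_rates(c(I27 = -1, I10 = 0, E = 0, G = 0, T = 0), p),
               "negative")
  expect_error(reaction_rates(c(I27 = 0, I10 = 0, E = 0, G = 0, T = 0), p,
                              f_inj = -1), "nonnegative")
  expect_error(reaction_rates(c(a = 1, b = 2), p), "five components")
})

test_that("matrix states evaluate row-wise like scalars", {
  u1 <- c(I27 = 100, I10 = 5, E = 1e6, G = 50, T = 1e8)
  u2 <- c(I27 = 0, I10 = 0, E = 0, G = 0, T = 3e8)
  um <- rbind(u1, u2)
  rm_ <- reaction_rates(um, p)
  expect_equal(unname(rm_[1, ]), unname(reaction_rates(u1, p)))
  expect_equal(unname(rm_[2, ]), unname(reaction_rates(u2, p)))
})
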