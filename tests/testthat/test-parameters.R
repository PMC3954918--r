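test_that("constructor validates signs and finiteness", {
  expect_s3_class(il27_parameters(), "il27_parameters")
  expect_error(il27_parameters(lamT = -1), "negative")
  expect_error(il27_parameters(d_I27 = 0), "strictly positive")
  expect_error(il27_parameters(D_T = NaN), "non-finite")
  expect_error(update_parameters(il27_parameters(), nosuch = 1), "unknown")
  expect_silent(il27_parameters(mu1 = 0))  # wild-type tumors secrete nothing
})

test_that("genotype masks zero exactly the knocked-out pathways", {
  p <- il27_parameters()
  ko <- apply_genotype(p, tcell_il10 = FALSE)
  expect_identical(ko$lam1, 0); expect_identical(ko$lam2, 0)
  expect_identical(ko$mu1, p$mu1)
  ctrl <- apply_genotype(p, tumor_il27 = FALSE)
  expect_identical(ctrl$mu1, 0)
  expect_identical(ctrl$lam1, p$lam1)
})

test_that("serialization round-trips through JSON and YAML", {
  p <- il27_parameters(lamT = 0.77,
                       paper_symbol = c(lamT = "lambda_T"))
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_parameters(p, f)
    q <- read_parameters(f)
    expect_equal(unclass(q)[names(param_units())],
                 unclass(p)[names(param_units())], tolerance = 1e-12)
    expect_equal(attr(q, "paper_symbol")[["lamT"]], "lambda_T")
    unlink(f)
  }
})

test_that("nondimensionalization round-trips to 1e-12 over random draws", {
  set.seed(42)
  for (i in 1:100) {
    vals <- lapply(unclass(il27_parameters()),
                   function(v) v * exp(stats::runif(1, -1, 1)))
    p <- do.call(il27_parameters, vals)
    s <- scale_set(time = exp(runif(1, -1, 1)), length = exp(runif(1, -1, 1)),
                   I27 = exp(runif(1, -2, 2)), I10 = exp(runif(1, -2, 2)),
                   E = exp(runif(1, -2, 2)), G = exp(runif(1, -2, 2)),
                   T = exp(runif(1, -2, 2)))
    back <- dimensionalize(nondimensionalize(p, s), s)
    expect_lt(max(rel_err(unlist(unclass(back)), unlist(unclass(p)))), 1e-12)
  }
})

test_that("a /day rate keeps its value under a 1-day time scale", {
  p <- il27_parameters(d_I10 = 9)
  dp <- nondimensionalize(p, default_scales(p))
  expect_identical(dp$d_I10, 9)
  expect_identical(dp$lamT, p$lamT)
})

test_that("unit-driven scaling matches hand-derived dimensional analysis", {
  p <- il27_parameters()
  s <- scale_set(time = 2, length = 0.5, I27 = 100, I10 = 10, E = 1e6,
                 G = 50, T = 1e9)
  dp <- nondimensionalize(p, s)
  # pg/cell/day: rate * t * producer-cell scale / product-concentration scale
  expect_equal(dp$mu1, p$mu1 * 2 * 1e9 / 100)
  expect_equal(dp$lam1, p$lam1 * 2 * 1e6 / 10)
  expect_equal(dp$lamG, p$lamG * 2 * 1e6 / 50)
  # cm^2/day: * t / L^2 ; cell/cm^3/day: * t / cell scale
  expect_equal(dp$D_I27, p$D_I27 * 2 / 0.25)
  expect_equal(dp$lamE, p$lamE * 2 / 1e6)
  # half-saturations divide by the species they gate
  expect_equal(dp$K_E2, p$K_E2 / 10)
  expect_equal(dp$K_killG, p$K_killG / 50)
  expect_equal(dp$T_max, p$T_max / 1e9)
  # identity scales leave everything unchanged
  ident <- scale_set()
  expect_equal(unclass(nondimensionalize(p, ident))[names(param_units())],
               unclass(p)[names(param_units())])
  expect_error(scale_set(time = 0), "positive")
})
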