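p <- il27_parameters()

test_that("nothing comes from nothing: zero initial state stays zero", {
  g <- build_grid(0.5, 32)
  init <- uniform_fields(g, c(0, 0, 0, 0, 0))
  tr <- simulate(p, g, t_end = 5, init = init,
                 settings = solver_settings(times = c(1, 5)))
  expect_identical(max(abs(tr$fields)), 0)
})

test_that("initial fields follow the scenario conventions", {
  g <- build_grid(0.5, 64)
  f <- initial_state(g, p, "wildtype", epsilon = 0.2, T0 = 1e8)
  expect_identical(max(f[, c("I27", "I10", "E", "G")]), 0)
  expect_identical(unname(f[65, "T"]), 0)             # vanishes at the boundary
  expect_equal(unname(f[1, "T"]), 1e8)        # maximal at the origin
  expect_true(all(diff(f[, "T"]) <= 0))
  ft <- initial_state(g, p, "transfected", epsilon = 0.2, T0 = 1e8)
  expect_equal(ft[, "I27"], p$mu1 / p$d_I27 * ft[, "T"])
  expect_error(initial_state(g, p, epsilon = 2), "epsilon")
})

test_that("a decoupled species decays as exp(-d t) to integrator tolerance", {
  g <- build_grid(0.5, 32)
  init <- uniform_fields(g, c(1000, 0, 0, 0, 0))  # only IL-27, no sources
  st <- solver_settings(rtol = 1e-10, atol = 1e-12, times = c(2, 5, 10))
  tr <- simulate(update_parameters(p, mu1 = 0), g, t_end = 10, init = init,
                 settings = st)
  for (d in c(2, 5, 10)) {
    f <- trajectory_fields(tr, d)
    expect_lt(max(rel_err(f[, "I27"], 1000 * exp(-p$d_I27 * d))), 1e-6)
  }
})

test_that("positivity holds along a baseline transfected run", {
  g <- build_grid(0.5, 64)
  tr <- simulate(p, g, t_end = 15)
  expect_gte(min(tr$fields), 0)
  expect_true(tr$containment_ok)
})

test_that("a domain too small for the tumor triggers the containment warning", {
  g <- build_grid(0.1, 32)
  expect_warning(
    simulate(update_parameters(p, mu1 = 0), g, t_end = 15,
             scenario = "wildtype", epsilon = 0.08, T0 = 3e8),
    "boundary")
})

test_that("halving the initial bump width leaves the treatment ordering
           unchanged (qualitative robustness)", {
  g <- build_grid(0.5, 64)
  st <- solver_settings(atol = 1e-10)
  loads <- sapply(c(0.25, 0.125), function(eps) {
    sapply(c(0, p$mu1), function(m) {
      tr <- simulate(update_parameters(p, mu1 = m), g, t_end = 15,
                     settings = st, epsilon = eps)
      tr$totals[nrow(tr$totals), "T"]
    })
  })
  # treated below control at both widths
  expect_lt(loads[2, 1], loads[1, 1])
  expect_lt(loads[2, 2], loads[1, 2])
})

test_that("trajectories export to tidy tables and a manifest", {
  g <- build_grid(0.5, 16)
  tr <- simulate(p, g, t_end = 2, settings = solver_settings(times = 0:2))
  df <- as.data.frame(tr)
  expect_setequal(names(df), c("time_day", "r_cm", "species", "value"))
  expect_equal(nrow(df), length(tr$times) * 17 * 5)
  tot <- as.data.frame(tr, what = "totals")
  expect_equal(nrow(tot), length(tr$times) * 5)
  # totals equal the quadrature of the stored fields
  i <- length(tr$times)
  expect_equal(unname(tr$totals[i, "T"]),
               total_amount(tr$fields[i, , "T"], g))
  d <- tempfile(); dir.create(d)
  paths <- write_trajectory(tr, d, "smoke", seed = 3L)
  expect_true(all(file.exists(paths)))
  man <- jsonlite::read_json(paths[["manifest"]], simplifyVector = TRUE)
  expect_equal(man$grid$N, 16)
  expect_equal(man$seed, 3)
  expect_match(man$parameter_hash, "^[a-f0-9]{32}$")
  unlink(d, recursive = TRUE)
})

test_that("solver rejects bad inputs", {
  g <- build_grid(0.5, 16)
  expect_error(simulate(p, g, t_end = -1), "t_end")
  expect_error(simulate(p, g, init = matrix(0, 3, 5)), "dimensions")
})
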