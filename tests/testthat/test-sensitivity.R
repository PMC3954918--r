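p <- il27_parameters()

test_that("default ranges cover the thirteen analyzed parameters", {
  rg <- parameter_ranges(p)
  expect_equal(nrow(rg), 13)
  expect_true(all(rg$lower < rg$upper))
  expect_true(all(rg$baseline >= rg$lower & rg$baseline <= rg$upper))
  expect_setequal(unique(rg$unit),
                  c("pg/cell/day", "cell/cm^3/day", "pg/cm^3", "/day",
                    "cell/cm^3"))
  bad <- rg; bad$lower[1] <- bad$upper[1] + 1
  expect_error(lhs_sample(bad, 10), "below")
})

test_that("Latin hypercube sampling is stratified and seed-deterministic", {
  rg <- parameter_ranges(p)
  n <- 40
  X <- lhs_sample(rg, n, seed = 5)
  expect_equal(dim(X), c(n, 13))
  for (j in seq_len(13)) {
    u <- (sort(X[, j]) - rg$lower[j]) / (rg$upper[j] - rg$lower[j])
    # k-th sorted value lies in the k-th of n equal strata
    expect_true(all(u > (seq_len(n) - 1) / n & u <= seq_len(n) / n))
  }
  expect_identical(lhs_sample(rg, n, seed = 5), X)
  expect_false(identical(lhs_sample(rg, n, seed = 6), X))
})

test_that("column means converge to the range midpoints", {
  rg <- parameter_ranges(p)
  means <- rowMeans(sapply(1:50, function(s) colMeans(lhs_sample(rg, 20, s))))
  mid <- (rg$lower + rg$upper) / 2
  se <- (rg$upper - rg$lower) / sqrt(12) / sqrt(50 * 20)
  expect_true(all(abs(means - mid) < 2 * se + 1e-12))
})

test_that("PRCC matches a brute-force rank-residual computation", {
  set.seed(31)
  n <- 12
  X <- cbind(a = runif(n), b = runif(n), c = runif(n))
  y <- 2 * X[, "a"] - X[, "b"]^2 + 0.3 * rnorm(n)
  got <- prcc(X, y)
  # independent oracle: explicit lm() on ranks, then residual correlation
  R <- apply(cbind(X, y), 2, rank)
  for (j in 1:3) {
    rx <- stats::residuals(stats::lm(R[, j] ~ R[, -c(j, 4), drop = FALSE]))
    ry <- stats::residuals(stats::lm(R[, 4] ~ R[, -c(j, 4), drop = FALSE]))
    r_oracle <- stats::cor(rx, ry)
    expect_lt(abs(got$prcc[j] - r_oracle), 1e-10)
    tval <- r_oracle * sqrt((n - 2 - 2) / (1 - r_oracle^2))
    expect_lt(abs(got$p_value[j] -
                  2 * stats::pt(abs(tval), n - 4, lower.tail = FALSE)),
              1e-10)
  }
})

test_that("PRCC isolates monotone signals with the right sign", {
  set.seed(17)
  n <- 500
  X <- matrix(runif(n * 13), n, 13,
              dimnames = list(NULL, paste0("x", 1:13)))
  y_up <- exp(3 * X[, 1])          # strictly increasing in x1 alone
  res <- prcc(X, y_up)
  expect_gt(res$prcc[1], 0.99)
  expect_true(all(abs(res$prcc[-1]) < 0.1))
  res_dn <- prcc(X, -y_up)
  expect_lt(res_dn$prcc[1], -0.99)
})

test_that("PRCC is a rank statistic: invariant to monotone transforms and
           row permutations, bounded by one", {
  set.seed(23)
  n <- 80
  X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  y <- X[, 1] - 2 * X[, 3] + 0.2 * rnorm(n)
  base <- prcc(X, y)
  expect_true(all(abs(base$prcc) <= 1))
  Xt <- X; Xt[, 1] <- X[, 1]^3; Xt[, 2] <- exp(X[, 2])
  expect_equal(prcc(Xt, exp(y))$prcc, base$prcc, tolerance = 1e-12)
  perm <- sample(n)
  expect_equal(prcc(X[perm, ], y[perm])$prcc, base$prcc, tolerance = 1e-12)
  Xc <- X; Xc[, 2] <- 1
  expect_error(prcc(Xc, y), "constant")
})

test_that("independent noise yields small PRCC magnitudes at n = 500", {
  set.seed(59)
  X <- matrix(runif(500 * 13), 500, 13,
              dimnames = list(NULL, paste0("x", 1:13)))
  res <- prcc(X, rnorm(500))
  expect_true(all(abs(res$prcc) < 0.1))
})

test_that("the tumor ratio behaves as a treatment-effect functional", {
  # identical treated and control systems give exactly 1
  expect_identical(tumor_ratio(update_parameters(p, mu1 = 0)), 1)
  # IL-27 secretion suppresses tumor relative to control
  expect_lt(tumor_ratio(p), 1)
  # stronger IL-10 killing monotonically strengthens the treatment effect
  ratios <- sapply(c(0.5, 1, 2), function(f)
    tumor_ratio(update_parameters(p, eta1 = p$eta1 * f)))
  expect_true(all(diff(ratios) < 0))
})

test_that("sensitivity runs are reproducible end to end", {
  rg <- parameter_ranges(p)
  s1 <- run_sensitivity(rg, n = 30, seed = 2, mode = "wellmixed")
  s2 <- run_sensitivity(rg, n = 30, seed = 2, mode = "wellmixed")
  expect_identical(s1$prcc, s2$prcc)
  expect_identical(s1$output, s2$output)
  f <- tempfile(fileext = ".csv")
  write_sensitivity(s1, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("csv$", "json", f)))
  unlink(c(f, sub("csv$", "json", f)))
})
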