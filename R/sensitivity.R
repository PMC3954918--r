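#' Parameter ranges for the sensitivity analysis
#'
#' The thirteen analyzed parameters: the three per-cell cytokine production
#' rates (`lam1`, `lam2`, `lamG`), the CTL activation rate (`lamE`), five
#' concentration half-saturations (`K_I27_10`, `K_E1`, `K_kill10`,
#' `K_killG`, `K_I27_G`), the CTL death rate and the two tumor kill rates
#' (`d_E`, `eta1`, `eta2`), and the carrying capacity (`T_max`).  Default
#' ranges span a factor of `factor` below/above the baseline.
#'
#' @param p baseline [il27_parameters()].
#' @param factor half-width of the range on a multiplicative scale.
#' @return Data frame of class `il27_ranges` with columns `parameter`,
#'   `lower`, `upper`, `baseline`, `unit`.
#' @export
parameter_ranges <- function(p = il27_parameters(), factor = 2) {
  stopifnot(inherits(p, "il27_parameters"), factor > 1)
  pars <- c("lam1", "lam2", "lamG", "lamE", "K_I27_10", "K_E1", "K_kill10",
            "K_killG", "K_I27_G", "d_E", "eta1", "eta2", "T_max")
  base <- unlist(p[pars])
  out <- data.frame(parameter = pars, lower = base / factor,
                    upper = base * factor, baseline = base,
                    unit = unname(param_units()[pars]),
                    row.names = NULL)
  class(out) <- c("il27_ranges", "data.frame")
  out
}

validate_ranges <- function(ranges) {
  req <- c("parameter", "lower", "upper", "baseline")
  if (!all(req %in% names(ranges)))
    stop("ranges must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(ranges$lower >= ranges$upper))
    stop("each lower bound must be below its upper bound", call. = FALSE)
  if (any(ranges$baseline < ranges$lower | ranges$baseline > ranges$upper))
    stop("baselines must lie inside their ranges", call. = FALSE)
  invisible(TRUE)
}

#' Latin hypercube sample over parameter ranges
#'
#' Stratified sampling: for each parameter, exactly one draw falls in each
#' of `n` equal-probability strata of `[lower, upper]`, with strata randomly
#' paired across parameters (via [lhs::randomLHS()]).
#'
#' @param ranges a [parameter_ranges()] data frame.
#' @param n number of samples (>= 2).
#' @param seed integer seed.
#' @return `n x nrow(ranges)` matrix with parameter names as columns.
#' @export
lhs_sample <- function(ranges, n, seed = 1L) {
  validate_ranges(ranges)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(ranges))
  x <- sweep(u, 2L, ranges$upper - ranges$lower, `*`)
  x <- sweep(x, 2L, ranges$lower, `+`)
  colnames(x) <- ranges$parameter
  x
}

#' Treated-to-control tumor ratio
#'
#' The sensitivity output functional: the ratio of tumor density under an
#' IL-27-secreting tumor (`mu1` as in `p`) to the matched non-secreting
#' control (`mu1 = 0`), all other parameters identical.  Values below 1 mean
#' IL-27 enhances tumor rejection.
#'
#' @param p an [il27_parameters()] with `mu1 > 0` for a treated/control
#'   contrast (at `mu1 = 0` the ratio is identically 1).
#' @param eval_time evaluation day.
#' @param eval_radius evaluation radius, cm (PDE mode only; the well-mixed
#'   surrogate has no space).
#' @param mode `"wellmixed"` (fast surrogate, default) or `"pde"`.
#' @param grid,settings,T0,epsilon PDE-mode controls, see [simulate()].
#' @return The dimensionless ratio.
#' @export
tumor_ratio <- function(p, eval_time = 15, eval_radius = 0,
                        mode = c("wellmixed", "pde"), grid = NULL,
                        settings = solver_settings(), T0 = 1e8,
                        epsilon = NULL) {
  stopifnot(inherits(p, "il27_parameters"))
  mode <- match.arg(mode)
  p_ctrl <- update_parameters(p, mu1 = 0)
  if (mode == "wellmixed") {
    trt <- simulate_wellmixed(p, times = eval_time, T0 = T0)
    ctl <- simulate_wellmixed(p_ctrl, times = eval_time, T0 = T0)
    num <- trt$T[nrow(trt)]
    den <- ctl$T[nrow(ctl)]
  } else {
    if (is.null(grid)) grid <- build_grid(R = 0.5, N = 200)
    if (is.null(epsilon)) epsilon <- 0.5 * grid$R
    if (eval_radius < 0 || eval_radius > grid$R)
      stop("eval_radius outside the domain", call. = FALSE)
    run1 <- simulate(p, grid, t_end = eval_time, settings = settings,
                     scenario = "transfected", T0 = T0, epsilon = epsilon)
    run0 <- simulate(p_ctrl, grid, t_end = eval_time, settings = settings,
                     scenario = "transfected", T0 = T0, epsilon = epsilon)
    num <- stats::approx(grid$r, trajectory_fields(run1, eval_time)[, "T"],
                         xout = eval_radius)$y
    den <- stats::approx(grid$r, trajectory_fields(run0, eval_time)[, "T"],
                         xout = eval_radius)$y
  }
  if (!is.finite(den) || den <= 0)
    stop("control tumor density vanished at the evaluation point; ",
         "ratio undefined", call. = FALSE)
  num / den
}

#' Partial rank correlation coefficients with p-values
#'
#' Ranks every input column and the output (ties get average ranks), then
#' for each parameter correlates the residuals of its ranks and the output
#' ranks after removing the linear dependence on all other ranked
#' parameters.  Implemented through the precision matrix of the ranked data;
#' p-values use the Student-t approximation
#' `t = r sqrt((n - 2 - k) / (1 - r^2))` with `k` the number of adjusted
#' covariates.
#'
#' @param X sample matrix (`n` rows, one column per parameter).
#' @param y output vector, `length(y) == nrow(X)`.
#' @return Data frame with columns `parameter`, `prcc`, `p_value`; attribute
#'   `n`.
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X) - 1L
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < ncol(X) + 2L)
    stop("need at least ncol(X) + 2 samples", call. = FALSE)
  const <- apply(X, 2L, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("PRCC undefined for constant column(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  R <- apply(cbind(X, y), 2L, rank)
  m <- ncol(R)
  r <- vapply(seq_len(m - 1L), function(j) {
    Z <- cbind(1, R[, -c(j, m), drop = FALSE])
    rx <- stats::.lm.fit(Z, R[, j])$residuals
    ry <- stats::.lm.fit(Z, R[, m])$residuals
    # an exactly explained variable has no remaining association
    if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) return(0)
    stats::cor(rx, ry)
  }, numeric(1))
  tval <- r * sqrt((n - 2L - k) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tval), df = n - 2L - k, lower.tail = FALSE)
  out <- data.frame(parameter = colnames(X) %||% paste0("x", seq_len(m - 1L)),
                    prcc = unname(r), p_value = unname(pval))
  attr(out, "n") <- n
  out
}

#' Latin hypercube / PRCC sensitivity analysis of the tumor ratio
#'
#' Samples the thirteen analyzed parameters over their ranges, evaluates the
#' treated/control tumor ratio for every sample and computes PRCCs with
#' p-values.  A negative PRCC means that increasing the parameter decreases
#' the ratio, i.e. increases the rejection of the IL-27-treated tumor
#' relative to control.
#'
#' @param ranges a [parameter_ranges()] data frame.
#' @param n number of Latin hypercube samples (paper-fidelity default 5000).
#' @param seed integer seed.
#' @param p_base baseline [il27_parameters()] supplying all non-analyzed
#'   parameters and the treated `mu1`.
#' @param eval_time,eval_radius evaluation point of the ratio.
#' @param mode `"wellmixed"` (surrogate, recommended for large `n`) or
#'   `"pde"`.
#' @param grid,settings PDE-mode controls.
#' @return An object of class `il27_sensitivity`: the [prcc()] data frame
#'   plus metadata (`n`, `seed`, `mode`, evaluation point) and the sample
#'   matrix/outputs as attributes.
#' @export
run_sensitivity <- function(ranges = parameter_ranges(), n = 5000,
                            seed = 1L, p_base = il27_parameters(),
                            eval_time = 15, eval_radius = 0,
                            mode = c("wellmixed", "pde"), grid = NULL,
                            settings = solver_settings()) {
  mode <- match.arg(mode)
  X <- lhs_sample(ranges, n, seed)
  y <- apply(X, 1L, function(row) {
    p <- do.call(update_parameters, c(list(p_base), as.list(row)))
    tumor_ratio(p, eval_time = eval_time, eval_radius = eval_radius,
                mode = mode, grid = grid, settings = settings)
  })
  res <- prcc(X, y)
  structure(list(prcc = res, n = n, seed = seed, mode = mode,
                 eval_time = eval_time, eval_radius = eval_radius,
                 sample = X, output = y),
            class = "il27_sensitivity")
}

#' @export
print.il27_sensitivity <- function(x, ...) {
  cat("LHS/PRCC sensitivity of the treated/control tumor ratio\n")
  cat("n =", x$n, " seed =", x$seed, " mode =", x$mode,
      " evaluated at day", x$eval_time, "\n")
  print(x$prcc, digits = 3)
  invisible(x)
}

#' Write sensitivity results as CSV plus a JSON manifest
#'
#' @param sens an `il27_sensitivity` object.
#' @param path CSV output path (`parameter, prcc, p_value`); the manifest
#'   goes alongside with extension `.json`.
#' @return Named character vector of paths, invisibly.
#' @export
write_sensitivity <- function(sens, path) {
  stopifnot(inherits(sens, "il27_sensitivity"))
  utils::write.csv(sens$prcc, path, row.names = FALSE)
  mpath <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(n = sens$n, seed = sens$seed, mode = sens$mode,
         eval_time = sens$eval_time, eval_radius = sens$eval_radius),
    mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = path, manifest = mpath))
}
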