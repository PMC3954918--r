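#' @name estimators
#' @title Closed-form two-time-point parameter estimators
#'
#' @description
#' The estimation recipes invert simplified, well-mixed versions of the model
#' equations between two observation times.  Each linear subsystem
#' `du/dt = P - d u` with constant source `P` has the solution
#' `u(t2) = P/d + (u(t1) - P/d) exp(-d (t2-t1))`, which is solved for `P`
#' (production estimators) or for `d` (effective death rate); the tumor
#' equation is log-linear and is solved for the net growth or the saturating
#' kill rate.  All estimators are exact algebraic inverses of their forward
#' models: recovery from noiseless consistently generated data is exact to
#' round-off.
NULL

# solution of du/dt = P - d*u at time t1+dt
lin_forward <- function(u1, P, d, dt) P / d + (u1 - P / d) * exp(-d * dt)

# inverse: constant source P from (u1, u2) a time dt apart
lin_source <- function(u1, u2, d, dt) {
  d * (u2 - u1 * exp(-d * dt)) / (1 - exp(-d * dt))
}

#' Net tumor growth rate from a volume series
#'
#' Mean over consecutive pairs of `ln(V(t2)/V(t1)) / (t2 - t1)`, the exact
#' inverse of exponential net growth `dV/dt = g V`.
#'
#' @param times observation days, strictly increasing, length >= 2.
#' @param values volumes (or densities), strictly positive.
#' @return Net growth rate `g`, /day.
#' @export
#' @examples
#' net_growth_from_series(c(0, 1, 2), c(1, 2, 4))   # log(2)
net_growth_from_series <- function(times, values) {
  if (length(times) < 2)
    stop("need at least two observations", call. = FALSE)
  if (length(times) != length(values))
    stop("times and values differ in length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values <= 0))
    stop("volumes must be strictly positive", call. = FALSE)
  mean(diff(log(values)) / diff(times))
}

#' Decay rate from a half-life
#'
#' @param halflife half-life, days (> 0).
#' @return `log(2) / halflife`, /day.
#' @export
rate_from_halflife <- function(halflife) {
  if (!is.finite(halflife) || halflife <= 0)
    stop("halflife must be positive", call. = FALSE)
  log(2) / halflife
}

#' Per-cell production rate from two concentration measurements
#'
#' Inverts `du/dt = a S - d u` (constant producer density `S`, known
#' degradation `d`) for the per-cell production rate `a`.
#'
#' @param u1,u2 concentrations at `t1` and `t2`, pg/cm^3.
#' @param t1,t2 observation days, `t2 > t1`.
#' @param source_density producer cell density `S`, cells/cm^3 (> 0).
#' @param d degradation rate, /day (> 0).
#' @return Production rate `a`, pg/cell/day.
#' @export
production_from_two_points <- function(u1, u2, t1, t2, source_density, d) {
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  if (!is.finite(source_density) || source_density <= 0)
    stop("source density must be positive (unidentifiable otherwise)",
         call. = FALSE)
  if (d <= 0) stop("degradation rate must be positive", call. = FALSE)
  lin_source(u1, u2, d, t2 - t1) / source_density
}

#' IL-27-enhanced IL-10 production rate
#'
#' Inverts `du/dt = lam1 E + lam2 E I27/(K + I27) - d u` (all bars denote
#' two-time-point averages held constant) for the enhancement `lam2`, given
#' the baseline rate `lam1`.
#'
#' @param u1,u2 IL-10 concentrations at `t1`, `t2`, pg/cm^3.
#' @param t1,t2 observation days, `t2 > t1`.
#' @param E_bar average CTL density, cells/cm^3 (> 0).
#' @param I27_bar average IL-27 concentration, pg/cm^3 (> 0 for
#'   identifiability).
#' @param K IL-27 half-saturation of the enhancement, pg/cm^3.
#' @param lam1 baseline production rate, pg/cell/day.
#' @param d IL-10 degradation rate, /day.
#' @return Enhancement rate `lam2`, pg/cell/day.
#' @export
enhanced_production <- function(u1, u2, t1, t2, E_bar, I27_bar, K, lam1, d) {
  if (!is.finite(I27_bar) || I27_bar <= 0)
    stop("I27_bar must be positive (lam2 unidentifiable at zero IL-27)",
         call. = FALSE)
  total <- production_from_two_points(u1, u2, t1, t2, E_bar, d)
  (total - lam1) / (I27_bar / (K + I27_bar))
}

#' CTL activation rate from two density measurements
#'
#' Inverts `dE/dt = lamE T/(K_T + T) - d E` (constant average tumor density
#' and known effective death rate) for the volumetric activation rate.
#'
#' @param E1,E5 CTL densities at `t1`, `t2`, cells/cm^3.
#' @param t1,t2 observation days, `t2 > t1`.
#' @param T_bar average tumor density, cells/cm^3 (> 0).
#' @param K_T activation half-saturation, cells/cm^3.
#' @param d_E_effective effective CTL death rate over the interval, /day.
#' @return Activation rate `lamE`, cells/cm^3/day.
#' @export
activation_rate <- function(E1, E5, t1, t2, T_bar, K_T, d_E_effective) {
  if (!is.finite(T_bar) || T_bar <= 0)
    stop("T_bar must be positive (unidentifiable otherwise)", call. = FALSE)
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  A <- lin_source(E1, E5, d_E_effective, t2 - t1)
  A / (T_bar / (K_T + T_bar))
}

#' Effective CTL death rate from two density measurements
#'
#' Solves `E(t2) = A/d + (E(t1) - A/d) exp(-d (t2-t1))` for `d` given the
#' constant activation source `A`; used to quantify the IL-27/IL-10
#' reduction of the CTL death rate in treated arms.
#'
#' @param E1,E5 CTL densities at `t1`, `t2`, cells/cm^3.
#' @param t1,t2 observation days, `t2 > t1`.
#' @param A constant activation source, cells/cm^3/day.
#' @return Effective death rate, /day.
#' @export
effective_death_rate <- function(E1, E5, t1, t2, A) {
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  dt <- t2 - t1
  f <- function(d) lin_forward(E1, A, d, dt) - E5
  # bracket: f is monotone decreasing in d for E1 above the source balance
  lo <- 1e-10; hi <- 1e3
  if (f(lo) * f(hi) > 0)
    stop("effective death rate not bracketed by the data", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

#' Saturating tumor kill rate from two density measurements
#'
#' Inverts `dT/dt = g T - eta T u/(K + u)` (net growth `g`, constant killer
#' concentration `u`) between two times:
#' `eta = (g - ln(T2/T1)/(t2-t1)) (K + u)/u`.
#'
#' @param T1,T2 tumor densities at `t1`, `t2`, cells/cm^3 (> 0).
#' @param t1,t2 observation days, `t2 > t1`.
#' @param net_growth net (kill-free) growth rate `g`, /day.
#' @param killer_bar average killer-cytokine concentration, pg/cm^3 (> 0).
#' @param K_kill killing half-saturation, pg/cm^3.
#' @return Kill rate `eta`, /day.
#' @export
killing_rate <- function(T1, T2, t1, t2, net_growth, killer_bar, K_kill) {
  if (T1 <= 0 || T2 <= 0)
    stop("tumor densities must be positive", call. = FALSE)
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  if (!is.finite(killer_bar) || killer_bar <= 0)
    stop("killer concentration must be positive (unidentifiable otherwise)",
         call. = FALSE)
  observed <- log(T2 / T1) / (t2 - t1)
  (net_growth - observed) * (K_kill + killer_bar) / killer_bar
}

#' Literature-fixed constants consumed by the estimation cascade
#'
#' Degradation rates, half-saturations and the tumor half-life are inputs to
#' the estimators, never estimated; defaults mirror the package baseline.
#'
#' @param p an [il27_parameters()] object supplying the defaults.
#' @param halflife tumor-cell half-life, days (gives `d_T`).
#' @return Named list of fixed constants.
#' @export
fixed_constants <- function(p = il27_parameters(), halflife = 2) {
  list(d_I27 = p$d_I27, d_I10 = p$d_I10, d_G = p$d_G, d_E = p$d_E,
       K_T = p$K_T, K_I27_10 = p$K_I27_10, K_I27_G = p$K_I27_G,
       K_kill10 = p$K_kill10, K_killG = p$K_killG, halflife = halflife)
}

#' Run the full estimation cascade on an observation set
#'
#' Executes the closed-form recipes in dependency order: net tumor growth
#' from the volume series; `d_T` from the half-life and `lamT = g + d_T`;
#' `mu1` from the IL-27 arm's IL-27 measurements; `lam1` from the
#' IL-10-competent control arm; `lam2` from the IL-27-treated competent arm;
#' `lamE` from the IL-10-knockout control arm (no survival modulation, so
#' the effective death rate equals `d_E`); the CTL-survival constant `K_E1`
#' from the knockout/IL-27 arm's reduced effective death rate, with
#' `K_E2 = kappa K_E1` (constrained solve); `lamG` from the competent
#' control arm; the IFN-gamma kill rate `eta2` from the knockout control arm
#' (no IL-10 killing); and the IL-10 kill rate `eta1` from the competent
#' control arm after subtracting the IFN-gamma contribution.
#'
#' Genotype contrasts are used exactly as in the source experiments: IL-10
#' knockout arms isolate IFN-gamma-mediated killing and the IL-27-secreting
#' tumor arms isolate IL-27-dependent terms.  Missing arms make only the
#' dependent parameters unestimable (`NA` with a reason); upstream estimates
#' are unchanged.
#'
#' @param obs an `il27_observations` object (see [generate_observations()]
#'   or [read_observations()]).
#' @param fixed list of literature-fixed constants, see [fixed_constants()].
#' @param kappa ratio `K_E2 / K_E1` of the constrained death-modulation
#'   solve.
#' @param averaging `"arithmetic"` (default) or `"geometric"` mean for the
#'   two-time-point averages.
#' @return An object of class `il27_estimates`: list with `estimates`
#'   (named numeric, `NA` where unestimable), `unestimable` (named character
#'   reasons), and `intermediates` (every average used).
#' @export
estimate_all <- function(obs, fixed = fixed_constants(), kappa = 0.1,
                         averaging = c("arithmetic", "geometric")) {
  stopifnot(inherits(obs, "il27_observations"))
  averaging <- match.arg(averaging)
  avg <- if (averaging == "arithmetic") function(x, y) (x + y) / 2
         else function(x, y) sqrt(x * y)
  est <- c(g = NA_real_, lamT = NA_real_, d_T = NA_real_, mu1 = NA_real_,
           lam1 = NA_real_, lam2 = NA_real_, lamE = NA_real_,
           K_E1 = NA_real_, K_E2 = NA_real_, lamG = NA_real_,
           eta1 = NA_real_, eta2 = NA_real_)
  why <- character(0)
  inter <- list()
  has <- function(arm) arm %in% names(obs$arms)
  t1 <- obs$days[1]; t2 <- obs$days[2]

  # net growth and tumor rates
  if (nrow(obs$tumor_volume) >= 2) {
    est["g"] <- net_growth_from_series(obs$tumor_volume$day,
                                       obs$tumor_volume$volume)
  } else why["g"] <- "tumor volume series too short"
  est["d_T"] <- rate_from_halflife(fixed$halflife)
  if (is.finite(est["g"])) est["lamT"] <- est["g"] + est["d_T"]
  else why["lamT"] <- "requires net growth g"

  # mu1 from an IL-27-secreting arm
  arm27 <- if (has("P1CTL_IL27")) "P1CTL_IL27"
           else if (has("IL10ko_P1CTL_IL27")) "IL10ko_P1CTL_IL27" else NULL
  if (!is.null(arm27)) {
    Tb <- bar2(obs, arm27, "T", avg)
    inter[[paste0("T_bar_", arm27)]] <- Tb
    est["mu1"] <- production_from_two_points(
      arm_value(obs, arm27, "I27", t1), arm_value(obs, arm27, "I27", t2),
      t1, t2, Tb, fixed$d_I27)
  } else why["mu1"] <- "no IL-27-secreting arm observed"

  # lam1, lamG from the IL-10-competent control arm
  if (has("P1CTL")) {
    Eb1 <- bar2(obs, "P1CTL", "E", avg)
    inter$E_bar_P1CTL <- Eb1
    est["lam1"] <- production_from_two_points(
      arm_value(obs, "P1CTL", "I10", t1), arm_value(obs, "P1CTL", "I10", t2),
      t1, t2, Eb1, fixed$d_I10)
    est["lamG"] <- production_from_two_points(
      arm_value(obs, "P1CTL", "G", t1), arm_value(obs, "P1CTL", "G", t2),
      t1, t2, Eb1, fixed$d_G)
  } else {
    why["lam1"] <- why["lamG"] <- "P1CTL arm missing"
  }

  # lam2 from the competent IL-27 arm
  if (has("P1CTL_IL27") && is.finite(est["lam1"])) {
    Eb27 <- bar2(obs, "P1CTL_IL27", "E", avg)
    I27b <- bar2(obs, "P1CTL_IL27", "I27", avg)
    inter$E_bar_P1CTL_IL27 <- Eb27
    inter$I27_bar_P1CTL_IL27 <- I27b
    est["lam2"] <- enhanced_production(
      arm_value(obs, "P1CTL_IL27", "I10", t1),
      arm_value(obs, "P1CTL_IL27", "I10", t2),
      t1, t2, Eb27, I27b, fixed$K_I27_10, est[["lam1"]], fixed$d_I10)
  } else if (!has("P1CTL_IL27")) {
    why["lam2"] <- "P1CTL/IL-27 arm missing"
  } else why["lam2"] <- "requires lam1"

  # lamE from the knockout control arm (effective death = d_E exactly)
  if (has("IL10ko_P1CTL")) {
    Tbko <- bar2(obs, "IL10ko_P1CTL", "T", avg)
    inter$T_bar_IL10ko_P1CTL <- Tbko
    est["lamE"] <- activation_rate(
      arm_value(obs, "IL10ko_P1CTL", "E", t1),
      arm_value(obs, "IL10ko_P1CTL", "E", t2),
      t1, t2, Tbko, fixed$K_T, fixed$d_E)
  } else why["lamE"] <- "IL-10-/-P1CTL arm missing"

  # survival constants from the knockout IL-27 arm
  if (has("IL10ko_P1CTL_IL27") && is.finite(est["lamE"])) {
    arm <- "IL10ko_P1CTL_IL27"
    Tbk27 <- bar2(obs, arm, "T", avg)
    A <- est[["lamE"]] * Tbk27 / (fixed$K_T + Tbk27)
    d_eff <- effective_death_rate(arm_value(obs, arm, "E", t1),
                                  arm_value(obs, arm, "E", t2), t1, t2, A)
    inter$d_eff_IL10ko_P1CTL_IL27 <- d_eff
    I27bk <- bar2(obs, arm, "I27", avg)
    inter$I27_bar_IL10ko_P1CTL_IL27 <- I27bk
    fac <- fixed$d_E / d_eff - 1
    if (fac <= 0) {
      why["K_E1"] <- "no death-rate reduction detected"
    } else {
      est["K_E1"] <- I27bk / fac
      est["K_E2"] <- kappa * est[["K_E1"]]
    }
  } else if (!has("IL10ko_P1CTL_IL27")) {
    why["K_E1"] <- why["K_E2"] <- "IL-10-/-P1CTL/IL-27 arm missing"
  } else why["K_E1"] <- why["K_E2"] <- "requires lamE"

  # eta2 from the knockout control arm, then eta1 from the competent arm
  if (has("IL10ko_P1CTL") && is.finite(est["g"])) {
    Gbko <- bar2(obs, "IL10ko_P1CTL", "G", avg)
    inter$G_bar_IL10ko_P1CTL <- Gbko
    est["eta2"] <- killing_rate(
      arm_value(obs, "IL10ko_P1CTL", "T", t1),
      arm_value(obs, "IL10ko_P1CTL", "T", t2),
      t1, t2, est[["g"]], Gbko, fixed$K_killG)
  } else if (!has("IL10ko_P1CTL")) {
    why["eta2"] <- "IL-10-/-P1CTL arm missing"
  } else why["eta2"] <- "requires net growth g"

  if (has("P1CTL") && is.finite(est["eta2"]) && is.finite(est["g"])) {
    Gb1 <- bar2(obs, "P1CTL", "G", avg)
    I10b1 <- bar2(obs, "P1CTL", "I10", avg)
    inter$G_bar_P1CTL <- Gb1
    inter$I10_bar_P1CTL <- I10b1
    g_resid <- est[["g"]] - est[["eta2"]] * Gb1 / (fixed$K_killG + Gb1)
    est["eta1"] <- killing_rate(
      arm_value(obs, "P1CTL", "T", t1), arm_value(obs, "P1CTL", "T", t2),
      t1, t2, g_resid, I10b1, fixed$K_kill10)
  } else if (!has("P1CTL")) {
    why["eta1"] <- "P1CTL arm missing"
  } else why["eta1"] <- "requires eta2 (IL-10-/- contrast) and g"

  structure(list(estimates = est, unestimable = why, intermediates = inter,
                 fixed = fixed, kappa = kappa, averaging = averaging),
            class = "il27_estimates")
}

# average of the two observation days for one arm/quantity
bar2 <- function(obs, arm, quantity, avg) {
  avg(arm_value(obs, arm, quantity, obs$days[1]),
      arm_value(obs, arm, quantity, obs$days[2]))
}

#' @export
print.il27_estimates <- function(x, ...) {
  cat("IL-27 model parameter estimates (", x$averaging,
      " two-point averages)\n", sep = "")
  print(data.frame(estimate = x$estimates))
  if (length(x$unestimable) > 0) {
    cat("unestimable:\n")
    for (nm in names(x$unestimable))
      cat("  ", nm, ": ", x$unestimable[[nm]], "\n", sep = "")
  }
  invisible(x)
}
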