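#' Pointwise reaction kinetics of the five-species network
#'
#' Evaluates the non-diffusive right-hand side of the model at one spatial
#' point (or vectorized over many points):
#' \deqn{dI27/dt = \mu_1 T - d_{I27} I27 + f_{inj}}
#' \deqn{dI10/dt = \lambda_1 E + \lambda_2 E \frac{I27}{K_{I27,10}+I27} - d_{I10} I10}
#' \deqn{dE/dt = \lambda_E \frac{T}{K_T+T} - d_E \frac{E}{1 + I27/K_{E1} + I10/K_{E2}}}
#' \deqn{dG/dt = \lambda_G E \frac{K_{I27,G}}{K_{I27,G}+I27} - d_G G}
#' \deqn{dT/dt = \lambda_T T (1-T/T_{max}) - d_T T
#'   - \eta_1 T \frac{I10}{K_{kill,10}+I10} - \eta_2 T \frac{G}{K_{kill,G}+G}}
#'
#' IL-27 is secreted by transfected tumor cells and/or injected; it enhances
#' CTL IL-10 production, reduces the CTL death rate (as does IL-10, more
#' weakly) and inhibits per-cell IFN-gamma production.  IL-10 and IFN-gamma
#' remove tumor cells through saturating kill terms.
#'
#' @param u state: numeric vector of length 5 named
#'   `I27, I10, E, G, T`, or a matrix with those five columns (one row per
#'   spatial point).
#' @param p an [il27_parameters()] object.
#' @param f_inj IL-27 injection source rate, pg/cm^3/day (scalar or one value
#'   per row of `u`).
#' @return Time derivatives in the same shape as `u`.
#' @export
#' @examples
#' p <- il27_parameters()
#' reaction_rates(c(I27 = 0, I10 = 0, E = 0, G = 0, T = 1e8), p)
reaction_rates <- function(u, p, f_inj = 0) {
  stopifnot(inherits(p, "il27_parameters"))
  um <- if (is.matrix(u)) u else matrix(u, nrow = 1,
                                        dimnames = list(NULL, names(u)))
  if (ncol(um) != 5)
    stop("state must have five components (I27, I10, E, G, T)",
         call. = FALSE)
  if (!is.null(colnames(um))) {
    if (!setequal(colnames(um), .species)) {
      stop("state names must be ", paste(.species, collapse = ", "),
           call. = FALSE)
    }
    um <- um[, .species, drop = FALSE]
  } else {
    colnames(um) <- .species
  }
  if (any(um < 0))
    stop("negative state component(s)", call. = FALSE)
  if (any(f_inj < 0))
    stop("injection rate must be nonnegative", call. = FALSE)
  out <- .reaction_rates(um, p, f_inj)
  if (is.matrix(u)) out else setNames(drop(out), .species)
}

.species <- c("I27", "I10", "E", "G", "T")

# unchecked core shared by the PDE and well-mixed integrators; callers are
# responsible for clamping near-zero undershoot
.reaction_rates <- function(um, p, f_inj = 0) {
  I27 <- um[, 1L]; I10 <- um[, 2L]; E <- um[, 3L]; G <- um[, 4L]
  TT <- um[, 5L]
  dI27 <- p$mu1 * TT - p$d_I27 * I27 + f_inj
  dI10 <- p$lam1 * E + p$lam2 * E * I27 / (p$K_I27_10 + I27) -
    p$d_I10 * I10
  dE <- p$lamE * TT / (p$K_T + TT) -
    p$d_E * E / (1 + I27 / p$K_E1 + I10 / p$K_E2)
  dG <- p$lamG * E * p$K_I27_G / (p$K_I27_G + I27) - p$d_G * G
  dT <- p$lamT * TT * (1 - TT / p$T_max) - p$d_T * TT -
    p$eta1 * TT * I10 / (p$K_kill10 + I10) -
    p$eta2 * TT * G / (p$K_killG + G)
  cbind(I27 = dI27, I10 = dI10, E = dE, G = dG, T = dT)
}
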