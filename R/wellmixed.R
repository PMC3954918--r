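#' Well-mixed (diffusion-free) simulation of the reaction network
#'
#' Integrates the five-species kinetics of [reaction_rates()] as a plain ODE
#' system, ignoring space.  This is the fast surrogate used by large
#' sensitivity studies and the independent oracle against which the PDE
#' solver is checked in the zero-diffusivity limit.  Genotype flags zero out
#' IL-10 production and/or tumor IL-27 secretion exactly as the experimental
#' knockout/control arms do.
#'
#' @param p an [il27_parameters()] object.
#' @param times output times, days.
#' @param T0 initial tumor density, cells/cm^3.
#' @param init optional named initial state (`I27, I10, E, G, T`); default
#'   is the transfected-tumor convention: tumor at `T0`, IL-27 at its
#'   quasi-steady ratio `mu1/d_I27 * T0`, all immune species zero.
#' @param tumor_il27,tcell_il10 genotype flags, see [apply_genotype()].
#' @param f_inj constant IL-27 source (pg/cm^3/day) or a function of time.
#' @param rtol,atol integrator tolerances (states are integrated unscaled;
#'   `atol` may be a length-5 vector).
#' @return Data frame with columns `time, I27, I10, E, G, T`.
#' @export
#' @examples
#' p <- il27_parameters()
#' simulate_wellmixed(p, times = c(0, 3, 9, 15))
simulate_wellmixed <- function(p, times, T0 = 1e8, init = NULL,
                               tumor_il27 = TRUE, tcell_il10 = TRUE,
                               f_inj = 0, rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(p, "il27_parameters"))
  p <- apply_genotype(p, tumor_il27 = tumor_il27, tcell_il10 = tcell_il10)
  if (is.null(init)) {
    init <- c(I27 = p$mu1 / p$d_I27 * T0, I10 = 0, E = 0, G = 0, T = T0)
  } else {
    init <- init[.species]
  }
  inj_fun <- if (is.function(f_inj)) f_inj else function(t) f_inj
  if (is.null(atol)) {
    sc <- species_scales(p)
    atol <- pmax(sc * 1e-12, 1e-12)
  }
  rhs <- function(t, y, parms) {
    y[y < 0] <- 0
    list(as.vector(.reaction_rates(matrix(y, nrow = 1L), p,
                                   f_inj = inj_fun(t))))
  }
  times <- sort(unique(c(times)))
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)
  out <- deSolve::ode(y = unname(init), times = times, func = rhs,
                      parms = NULL, method = "lsoda", rtol = rtol,
                      atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("well-mixed integrator failed", call. = FALSE)
  df <- as.data.frame(out)
  names(df) <- c("time", .species)
  if (prepend) df <- df[-1L, , drop = FALSE]
  rownames(df) <- NULL
  df
}
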