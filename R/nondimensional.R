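#' Characteristic scales for nondimensionalization
#'
#' @param time time scale in days.
#' @param length length scale in cm.
#' @param I27,I10,G reference cytokine concentrations, pg/cm^3.
#' @param E,T reference cell densities, cells/cm^3.
#' @return An object of class `il27_scales`.
#' @seealso [default_scales()], [nondimensionalize()]
#' @export
scale_set <- function(time = 1, length = 1, I27 = 1, I10 = 1, E = 1, G = 1,
                      T = 1) {
  s <- list(time = time, length = length,
            species = c(I27 = I27, I10 = I10, E = E, G = G, T = T))
  if (!all(is.finite(unlist(s))) || any(unlist(s) <= 0))
    stop("all scales must be finite and strictly positive", call. = FALSE)
  structure(s, class = "il27_scales")
}

#' Default scale set implied by a parameter set
#'
#' One day for time, the domain radius for length, the carrying capacity for
#' both cell densities and each cytokine's principal half-saturation for
#' concentrations.  With a 1-day time scale, first-order rates (unit /day)
#' keep their numerical values in dimensionless form.
#'
#' @param p an [il27_parameters()] object.
#' @param R domain radius in cm (length scale).
#' @return An `il27_scales` object.
#' @export
default_scales <- function(p, R = 0.5) {
  stopifnot(inherits(p, "il27_parameters"))
  scale_set(time = 1, length = R,
            I27 = p$K_I27_10, I10 = p$K_kill10, E = p$T_max, G = p$K_killG,
            T = p$T_max)
}

scaling_factor <- function(name, s) {
  sc <- .param_scaling[[name]]
  f <- 1
  if (!is.null(sc$t)) f <- f * s$time^sc$t
  if (!is.null(sc$L)) f <- f * s$length^sc$L
  if (!is.null(sc$num)) f <- f * s$species[[sc$num]]
  if (!is.null(sc$den)) f <- f / s$species[[sc$den]]
  f
}

#' Nondimensionalize a parameter set
#'
#' Rescales every parameter according to its units: first-order rates are
#' multiplied by the time scale, diffusivities by time/length^2, per-cell
#' production rates by time * producer-cell scale / product-concentration
#' scale, half-saturations are divided by the matching species scale.
#'
#' @param p an [il27_parameters()] object.
#' @param s an [scale_set()] object.
#' @return An object of class `il27_dimensionless`: named list of rescaled
#'   parameters with the generating scales attached.
#' @seealso [dimensionalize()]
#' @export
nondimensionalize <- function(p, s) {
  stopifnot(inherits(p, "il27_parameters"), inherits(s, "il27_scales"))
  dp <- lapply(names(param_units()),
               function(nm) p[[nm]] * scaling_factor(nm, s))
  names(dp) <- names(param_units())
  structure(dp, class = "il27_dimensionless", scales = s)
}

#' Restore dimensional parameters from their dimensionless images
#'
#' Exact inverse of [nondimensionalize()].
#'
#' @param dp an `il27_dimensionless` object.
#' @param s the generating [scale_set()]; defaults to the one stored in `dp`.
#' @return An [il27_parameters()] object.
#' @export
dimensionalize <- function(dp, s = attr(dp, "scales")) {
  stopifnot(inherits(dp, "il27_dimensionless"), inherits(s, "il27_scales"))
  vals <- lapply(names(param_units()),
                 function(nm) dp[[nm]] / scaling_factor(nm, s))
  names(vals) <- names(param_units())
  do.call(il27_parameters, vals)
}
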