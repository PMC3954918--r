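#' Model parameters for the IL-27 tumor-immune network
#'
#' Constructs the full dimensional parameter set of the five-species model
#' (IL-27, IL-10, activated CD8+ T cells, IFN-gamma, tumor cells).  Every
#' argument has a package default forming a self-consistent baseline; any
#' subset can be overridden.
#'
#' Units are fixed throughout the package: time in days, length in cm,
#' cytokine concentrations in pg/cm^3 and cell densities in cells/cm^3.
#'
#' @param D_I27,D_I10,D_E,D_G,D_T diffusion (cells: dispersion) coefficients,
#'   cm^2/day.
#' @param mu1 IL-27 production rate per transfected tumor cell, pg/cell/day.
#'   Zero for wild-type (non-secreting) tumor cells.
#' @param d_I27 IL-27 degradation rate, /day.
#' @param lam1 baseline IL-10 production per CTL (no IL-27), pg/cell/day.
#' @param lam2 maximal IL-27-enhanced IL-10 production per CTL, pg/cell/day.
#' @param K_I27_10 IL-27 half-saturation in the IL-10 enhancement, pg/cm^3.
#' @param d_I10 IL-10 degradation rate, /day.
#' @param lamE maximal CTL activation rate by tumor antigen, cells/cm^3/day.
#' @param K_T tumor-density half-saturation of CTL activation, cells/cm^3.
#' @param K_E1,K_E2 IL-27 and IL-10 half-saturations in the CTL death-rate
#'   reduction, pg/cm^3.
#' @param d_E CTL death rate in the absence of survival cytokines, /day.
#' @param lamG maximal IFN-gamma production per CTL, pg/cell/day.
#' @param K_I27_G IL-27 half-saturation in IFN-gamma inhibition, pg/cm^3.
#' @param d_G IFN-gamma degradation rate, /day.
#' @param lamT maximal tumor proliferation rate, /day.
#' @param T_max tumor carrying capacity, cells/cm^3.
#' @param d_T tumor death rate, /day.
#' @param eta1 maximal IL-10-mediated tumor kill rate, /day.
#' @param K_kill10 IL-10 half-saturation in tumor killing, pg/cm^3.
#' @param eta2 maximal IFN-gamma-mediated tumor kill rate, /day.
#' @param K_killG IFN-gamma half-saturation in tumor killing, pg/cm^3.
#' @param paper_symbol optional named character vector annotating parameters
#'   with the symbols used in an external source; carried through
#'   serialization untouched.
#'
#' @return An object of class `il27_parameters`: a named list of the 26
#'   parameters with a `paper_symbol` attribute.
#' @seealso [reaction_rates()], [nondimensionalize()], [write_parameters()]
#' @export
#' @examples
#' p <- il27_parameters()                    # baseline transfected tumor
#' p0 <- il27_parameters(mu1 = 0)            # wild-type (J558-Ctrl-like)
il27_parameters <- function(D_I27 = 8.64e-2, D_I10 = 8.64e-2, D_E = 8.64e-4,
                            D_G = 8.64e-2, D_T = 8.64e-6,
                            mu1 = 1e-5, d_I27 = 1.38889,
                            lam1 = 2e-5, lam2 = 2.5e-4, K_I27_10 = 2000,
                            d_I10 = 9,
                            lamE = 5.8e5, K_T = 1e7, K_E1 = 600, K_E2 = 60,
                            d_E = 1.4,
                            lamG = 3e-4, K_I27_G = 1e4, d_G = 1.404,
                            lamT = 0.69, T_max = 1e9, d_T = log(2) / 2,
                            eta1 = 1.0, K_kill10 = 25, eta2 = 0.4,
                            K_killG = 400,
                            paper_symbol = NULL) {
  p <- mget(names(param_units()))
  p <- lapply(p, as.numeric)
  validate_parameters(p)
  structure(p, class = "il27_parameters", paper_symbol = paper_symbol)
}

#' Units of every model parameter
#'
#' @return Named character vector mapping each canonical parameter name to its
#'   unit string.
#' @export
param_units <- function() {
  c(D_I27 = "cm^2/day", D_I10 = "cm^2/day", D_E = "cm^2/day",
    D_G = "cm^2/day", D_T = "cm^2/day",
    mu1 = "pg/cell/day", d_I27 = "/day",
    lam1 = "pg/cell/day", lam2 = "pg/cell/day", K_I27_10 = "pg/cm^3",
    d_I10 = "/day",
    lamE = "cell/cm^3/day", K_T = "cell/cm^3", K_E1 = "pg/cm^3",
    K_E2 = "pg/cm^3", d_E = "/day",
    lamG = "pg/cell/day", K_I27_G = "pg/cm^3", d_G = "/day",
    lamT = "/day", T_max = "cell/cm^3", d_T = "/day",
    eta1 = "/day", K_kill10 = "pg/cm^3", eta2 = "/day", K_killG = "pg/cm^3")
}

# species each scaled quantity refers to: producer cell -> product species for
# per-cell rates; the species whose concentration a half-saturation divides.
.param_scaling <- list(
  D_I27 = list(t = 1, L = -2), D_I10 = list(t = 1, L = -2),
  D_E = list(t = 1, L = -2), D_G = list(t = 1, L = -2),
  D_T = list(t = 1, L = -2),
  mu1 = list(t = 1, num = "T", den = "I27"), d_I27 = list(t = 1),
  lam1 = list(t = 1, num = "E", den = "I10"),
  lam2 = list(t = 1, num = "E", den = "I10"),
  K_I27_10 = list(den = "I27"), d_I10 = list(t = 1),
  lamE = list(t = 1, den = "E"), K_T = list(den = "T"),
  K_E1 = list(den = "I27"), K_E2 = list(den = "I10"), d_E = list(t = 1),
  lamG = list(t = 1, num = "E", den = "G"), K_I27_G = list(den = "I27"),
  d_G = list(t = 1),
  lamT = list(t = 1), T_max = list(den = "T"), d_T = list(t = 1),
  eta1 = list(t = 1), K_kill10 = list(den = "I10"),
  eta2 = list(t = 1), K_killG = list(den = "G"))

.strictly_positive <- c("D_I27", "D_I10", "D_E", "D_G", "D_T",
                        "d_I27", "d_I10", "d_E", "d_G", "d_T",
                        "K_I27_10", "K_T", "K_E1", "K_E2", "K_I27_G",
                        "K_kill10", "K_killG", "T_max")

validate_parameters <- function(p) {
  nm <- names(param_units())
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- unlist(p[nm])
  if (!all(is.finite(vals)))
    stop("non-finite parameter value(s): ",
         paste(nm[!is.finite(vals)], collapse = ", "), call. = FALSE)
  if (any(vals < 0))
    stop("negative parameter value(s): ",
         paste(nm[vals < 0], collapse = ", "), call. = FALSE)
  sp <- unlist(p[.strictly_positive])
  if (any(sp <= 0))
    stop("parameter(s) must be strictly positive: ",
         paste(.strictly_positive[sp <= 0], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.il27_parameters <- function(x, ...) {
  cat("IL-27 tumor-immune model parameters\n")
  df <- data.frame(value = unlist(x), unit = param_units()[names(x)])
  print(df, ...)
  invisible(x)
}

#' Modify a parameter set
#'
#' @param p an [il27_parameters()] object.
#' @param ... name = value overrides.
#' @return A validated `il27_parameters` object.
#' @export
update_parameters <- function(p, ...) {
  stopifnot(inherits(p, "il27_parameters"))
  ov <- list(...)
  if (length(ov) == 0) return(p)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(ov)] <- lapply(ov, as.numeric)
  validate_parameters(p)
  p
}

#' Apply an experimental genotype to a parameter set
#'
#' The source experiments cross two tumor lines with two T-cell genotypes:
#' tumor cells either secrete IL-27 (transfected, `mu1 > 0`) or do not
#' (control, `mu1 = 0`), and CTLs either produce IL-10 or carry an IL-10
#' knockout (`lam1 = lam2 = 0`).
#'
#' @param p an [il27_parameters()] object.
#' @param tumor_il27 logical; `FALSE` zeroes `mu1` (control tumor line).
#' @param tcell_il10 logical; `FALSE` zeroes `lam1` and `lam2` (IL-10
#'   knockout CTLs).
#' @return The masked `il27_parameters` object.
#' @export
apply_genotype <- function(p, tumor_il27 = TRUE, tcell_il10 = TRUE) {
  stopifnot(inherits(p, "il27_parameters"))
  if (!tumor_il27) p <- update_parameters(p, mu1 = 0)
  if (!tcell_il10) p <- update_parameters(p, lam1 = 0, lam2 = 0)
  p
}

#' IL-27 production ladder for the transfected-tumor dose study
#'
#' Ordered per-cell IL-27 secretion rates for the four simulated cases:
#' control tumor cells and transfected lines with small, moderate and large
#' production.
#'
#' @return Named numeric vector (pg/cell/day).
#' @export
mu1_ladder <- function() {
  c(none = 0, small = 2e-6, moderate = 5e-6, large = 1e-5)
}

#' Serialize parameters to JSON or YAML
#'
#' Writes canonical names, values, units and any `paper_symbol` annotation.
#'
#' @param p an [il27_parameters()] object.
#' @param path output file; format inferred from the extension
#'   (`.json`, `.yaml`/`.yml`) unless `format` is given.
#' @param format `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path, format = NULL) {
  stopifnot(inherits(p, "il27_parameters"))
  format <- format %||% guess_format(path)
  sym <- attr(p, "paper_symbol")
  obj <- list(parameters = as.list(unclass(p)),
              units = as.list(param_units()))
  if (!is.null(sym)) obj$paper_symbol <- as.list(sym)
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path, precision = 15)
  }
  invisible(path)
}

#' Read parameters written by [write_parameters()]
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return An `il27_parameters` object.
#' @export
read_parameters <- function(path) {
  obj <- if (guess_format(path) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- obj$parameters
  sym <- obj$paper_symbol
  do.call(il27_parameters,
          c(vals[names(vals) %in% names(param_units())],
            list(paper_symbol = if (is.null(sym)) NULL else unlist(sym))))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return("json")
  if (ext %in% c("yaml", "yml")) return("yaml")
  stop("cannot infer format from extension: ", path, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
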