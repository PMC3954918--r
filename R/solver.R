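#' Numerical settings for the PDE solver
#'
#' @param rtol,atol relative/absolute tolerances handed to the stiff
#'   integrator.  Integration is performed in species-scaled variables (each
#'   species divided by its reference scale), so `atol` is dimensionless.
#' @param max_step maximal internal step, days.
#' @param positivity_tol largest tolerated undershoot below zero in scaled
#'   variables; worse undershoot raises an error, smaller undershoot is
#'   floored to zero in the output.
#' @param times optional explicit output times (days); default is a uniform
#'   sampling of the horizon.
#' @return An object of class `il27_solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-6, atol = 1e-9, max_step = Inf,
                            positivity_tol = 1e-6, times = NULL) {
  if (rtol <= 0 || atol <= 0 || positivity_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 positivity_tol = positivity_tol, times = times),
            class = "il27_solver_settings")
}

#' Initial fields on the radial grid
#'
#' The tumor starts as a smooth compactly supported bump at the origin,
#' `T(r, 0) = T0 (1 - (r/epsilon)^2)^2` for `r < epsilon`, zero beyond.
#' There are no activated CD8+ T cells initially, hence no IL-10 and no
#' IFN-gamma.  For a transfected tumor the initial IL-27 profile mirrors the
#' tumor profile at its quasi-steady ratio `mu1/d_I27`; for a wild-type
#' (non-secreting) tumor IL-27 starts at zero and `mu1` is ignored by the
#' caller.
#'
#' @param grid an [build_grid()] grid.
#' @param p an [il27_parameters()] object.
#' @param scenario `"transfected"` or `"wildtype"`.
#' @param epsilon bump width, cm, in `(0, R]`.
#' @param T0 peak tumor density, cells/cm^3.
#' @return A `(N+1) x 5` matrix of class `il27_fields` (columns
#'   `I27, I10, E, G, T`) with attribute `time = 0`.
#' @export
initial_state <- function(grid, p, scenario = c("transfected", "wildtype"),
                          epsilon = 0.5 * grid$R, T0 = 3e8) {
  stopifnot(inherits(grid, "il27_grid"), inherits(p, "il27_parameters"))
  scenario <- match.arg(scenario)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon > grid$R)
    stop("epsilon must lie in (0, R]", call. = FALSE)
  r <- grid$r
  Tf <- ifelse(r < epsilon, T0 * (1 - (r / epsilon)^2)^2, 0)
  I27 <- if (scenario == "transfected") p$mu1 / p$d_I27 * Tf else 0 * Tf
  f <- cbind(I27 = I27, I10 = 0 * r, E = 0 * r, G = 0 * r, T = Tf)
  structure(f, class = "il27_fields", time = 0)
}

# per-species reference scales for the internally scaled integration
species_scales <- function(p) {
  c(I27 = p$K_I27_10, I10 = p$K_kill10, E = p$T_max, G = p$K_killG,
    T = p$T_max)
}

#' Simulate the radially symmetric tumor-immune model
#'
#' Method of lines: the conservative finite-volume spherical Laplacian
#' ([radial_laplacian()]) couples the nodes, [reaction_rates()] supplies the
#' pointwise kinetics, and an optional [injection_protocol()] adds the
#' therapeutic IL-27 source.  Time integration uses the adaptive stiff
#' solver from \pkg{deSolve} (banded Jacobian via `ode.1D`), split at
#' protocol switch times so the integrator never steps across a source
#' discontinuity.
#'
#' @param p an [il27_parameters()] object.
#' @param grid an [build_grid()] grid.
#' @param protocol an [injection_protocol()] or `NULL` for no injection.
#' @param t_end horizon, days.
#' @param settings an [solver_settings()] object.
#' @param scenario,epsilon,T0 initial-condition controls, see
#'   [initial_state()]; ignored when `init` is supplied.
#' @param init optional explicit initial `il27_fields` matrix.
#' @param D_override optional named numeric vector overriding diffusivities
#'   (used by conservation and convergence checks), e.g. `c(T = 0)`.
#' @param reactions_off logical; `TRUE` integrates diffusion only.
#' @return An object of class `il27_trajectory`: list with `times`, `fields`
#'   (array time x node x species), `totals` (matrix time x species, by
#'   shell quadrature), `grid`, `params`, `protocol`, `settings`,
#'   `containment_ok`.
#' @export
simulate <- function(p, grid, protocol = NULL, t_end = 15,
                     settings = solver_settings(),
                     scenario = c("transfected", "wildtype"),
                     epsilon = 0.5 * grid$R, T0 = 3e8, init = NULL,
                     D_override = NULL, reactions_off = FALSE) {
  stopifnot(inherits(p, "il27_parameters"), inherits(grid, "il27_grid"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0",
                                            call. = FALSE)
  scenario <- match.arg(scenario)
  if (scenario == "wildtype") p <- update_parameters(p, mu1 = 0)
  if (is.null(init)) init <- initial_state(grid, p, scenario, epsilon, T0)
  if (!all(dim(init) == c(grid$N + 1L, 5L)))
    stop("init has wrong dimensions for the grid", call. = FALSE)
  if (is.null(protocol)) protocol <- injection_protocol("none")

  D <- c(I27 = p$D_I27, I10 = p$D_I10, E = p$D_E, G = p$D_G, T = p$D_T)
  if (!is.null(D_override)) D[names(D_override)] <- D_override
  scales <- species_scales(p)
  n <- grid$N + 1L
  inj_shape <- exp(-protocol$decay_gamma * (grid$R - grid$r))
  fa_h <- grid$face_areas / grid$h
  vol <- grid$volumes

  rhs <- function(t, y, parms) {
    um <- matrix(y, nrow = n, ncol = 5L)
    um <- sweep(um, 2L, scales, `*`)
    um[um < 0] <- 0
    du <- .reaction_rates(um, p,
                          f_inj = inj_shape * injection_amplitude(t, protocol))
    if (reactions_off) du[] <- 0
    # conservative diffusion, zero flux at r = 0 and r = R
    flux <- fa_h * diff(um)            # matrix (n-1) x 5, per species
    lap <- (rbind(flux, 0) - rbind(0, flux)) / vol
    du <- du + sweep(lap, 2L, D, `*`)
    list(as.vector(sweep(du, 2L, scales, `/`)))
  }

  times <- settings$times %||% seq(0, t_end, length.out = 151L)
  times <- sort(unique(c(0, times[times <= t_end], t_end)))
  y0 <- as.vector(sweep(unclass(init), 2L, scales, `/`))

  segs <- c(0, protocol_switch_times(protocol, t_end), t_end)
  out <- NULL
  y <- y0
  for (k in seq_len(length(segs) - 1L)) {
    tt <- times[times >= segs[k] & times <= segs[k + 1L]]
    tt <- sort(unique(c(segs[k], tt, segs[k + 1L])))
    seg_out <- deSolve::ode.1D(y = y, times = tt, func = rhs, parms = NULL,
                               nspec = 5L, dimens = n, method = "lsoda",
                               rtol = settings$rtol, atol = settings$atol,
                               hmax = settings$max_step)
    if (attr(seg_out, "istate")[1L] < 0)
      stop("stiff integrator failed in [", segs[k], ", ", segs[k + 1L],
           "] days; diagnostics: istate = ", attr(seg_out, "istate")[1L],
           call. = FALSE)
    y <- as.numeric(seg_out[nrow(seg_out), -1L])
    keep <- seg_out[, 1L] %in% times
    if (!is.null(out)) keep[1L] <- FALSE   # drop duplicated seam point
    out <- rbind(out, seg_out[keep, , drop = FALSE])
  }

  undershoot <- -min(out[, -1L], 0)
  if (undershoot > settings$positivity_tol)
    stop("positivity violated: undershoot ", signif(undershoot, 3),
         " exceeds tolerance ", settings$positivity_tol, call. = FALSE)

  nt <- nrow(out)
  fields <- array(pmax(out[, -1L, drop = FALSE], 0), dim = c(nt, n, 5L),
                  dimnames = list(NULL, NULL, .species))
  for (s in seq_len(5L)) fields[, , s] <- fields[, , s] * scales[s]
  totals <- sapply(.species, function(s) fields[, , s] %*% vol)
  if (nt == 1L) totals <- matrix(totals, nrow = 1L,
                                 dimnames = list(NULL, .species))

  containment_ok <- max(fields[, n, "T"]) <= 1e-6 * p$T_max
  if (!containment_ok)
    warning("tumor density at the boundary exceeds 1e-6 * T_max; ",
            "enlarge the domain radius R", call. = FALSE)

  structure(list(times = out[, 1L], fields = fields, totals = totals,
                 grid = grid, params = p, protocol = protocol,
                 settings = settings, scenario = scenario,
                 containment_ok = containment_ok),
            class = "il27_trajectory")
}

#' Extract the fields at (or nearest to) a given day
#'
#' @param traj an `il27_trajectory`.
#' @param day requested time, days.
#' @return An `il27_fields` matrix with attribute `time` set to the actual
#'   stored time.
#' @export
trajectory_fields <- function(traj, day) {
  stopifnot(inherits(traj, "il27_trajectory"))
  i <- which.min(abs(traj$times - day))
  f <- traj$fields[i, , ]
  colnames(f) <- .species
  structure(f, class = "il27_fields", time = traj$times[i])
}

#' @export
print.il27_trajectory <- function(x, ...) {
  cat("IL-27 model trajectory:", length(x$times), "output times over",
      max(x$times), "days;", x$grid$N + 1L, "radial nodes (R =", x$grid$R,
      "cm)\n")
  cat("final totals:\n")
  print(x$totals[nrow(x$totals), ])
  invisible(x)
}

#' Tidy data frame of a trajectory
#'
#' @param x an `il27_trajectory`.
#' @param row.names,optional unused (S3 signature).
#' @param what `"fields"` for the long node-level table (columns `time_day`,
#'   `r_cm`, `species`, `value`) or `"totals"` for per-time totals.
#' @param ... unused.
#' @export
as.data.frame.il27_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE,
                                          what = c("fields", "totals"),
                                          ...) {
  what <- match.arg(what)
  if (what == "totals") {
    return(data.frame(time_day = rep(x$times, 5L),
                      species = rep(.species, each = length(x$times)),
                      total = as.vector(x$totals)))
  }
  nt <- length(x$times); nn <- x$grid$N + 1L
  data.frame(time_day = rep(x$times, times = nn * 5L),
             r_cm = rep(rep(x$grid$r, each = nt), times = 5L),
             species = rep(.species, each = nt * nn),
             value = as.vector(x$fields))
}

#' Write trajectory CSVs and a JSON run manifest
#'
#' Produces `<prefix>_fields.csv` (tidy long format), `<prefix>_totals.csv`
#' and `<prefix>_manifest.json` (grid, settings, parameter hash, protocol).
#'
#' @param traj an `il27_trajectory`.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @param seed optional seed to record in the manifest.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_trajectory <- function(traj, dir, prefix = "run", seed = NULL) {
  stopifnot(inherits(traj, "il27_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fields = file.path(dir, paste0(prefix, "_fields.csv")),
             totals = file.path(dir, paste0(prefix, "_totals.csv")),
             manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  utils::write.csv(as.data.frame(traj, what = "fields"), paths["fields"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(traj, what = "totals"), paths["totals"],
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("il27sim")),
    grid = list(R = traj$grid$R, N = traj$grid$N),
    scenario = traj$scenario,
    protocol = unclass(traj$protocol),
    settings = unclass(traj$settings)[c("rtol", "atol", "positivity_tol")],
    parameters = as.list(unclass(traj$params)),
    parameter_hash = parameter_hash(traj$params),
    seed = seed,
    containment_ok = traj$containment_ok)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# md5 of the canonical JSON serialization of a parameter set
parameter_hash <- function(p) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(as.list(unclass(p)), tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}
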