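#' Design of a synthetic observation study
#'
#' Describes the measurement schedule the estimation cascade expects: a
#' tumor-volume series over the third week of growth and two-time-point
#' (default days 1 and 5) cell and cytokine measurements in four genotype
#' arms crossing tumor IL-27 secretion with CTL IL-10 competence.
#'
#' @param volume_days tumor-volume measurement days.
#' @param cell_days the two cell/cytokine measurement days.
#' @param genotypes subset of
#'   `c("P1CTL", "IL10ko_P1CTL", "P1CTL_IL27", "IL10ko_P1CTL_IL27")`.
#' @param occupied_volume volume (cm^3) the measured cells occupy; converts
#'   densities to counts in exports.
#' @param cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 = deterministic).
#' @param seed integer seed fixing all randomness.
#' @param T1 tumor density at the first cell day, cells/cm^3.
#' @param E1 transferred-CTL density at the first cell day, cells/cm^3.
#' @param V1 tumor volume at the first volume day, mm^3.
#' @return An object of class `il27_obs_design`.
#' @export
observation_design <- function(volume_days = c(11, 14, 17, 20),
                               cell_days = c(1, 5),
                               genotypes = c("P1CTL", "IL10ko_P1CTL",
                                             "P1CTL_IL27",
                                             "IL10ko_P1CTL_IL27"),
                               occupied_volume = 0.05, cv = 0.1,
                               seed = 1L, T1 = 3e8, E1 = 8e6, V1 = 50) {
  if (any(diff(volume_days) <= 0) || any(volume_days <= 0))
    stop("volume_days must be positive and increasing", call. = FALSE)
  if (length(cell_days) != 2 || diff(cell_days) <= 0 || any(cell_days <= 0))
    stop("cell_days must be two increasing positive days", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  genotypes <- match.arg(genotypes, several.ok = TRUE)
  structure(list(volume_days = volume_days, cell_days = cell_days,
                 genotypes = genotypes, occupied_volume = occupied_volume,
                 cv = cv, seed = as.integer(seed), T1 = T1, E1 = E1,
                 V1 = V1),
            class = "il27_obs_design")
}

.genotype_flags <- list(
  P1CTL             = c(tumor_il27 = FALSE, tcell_il10 = TRUE),
  IL10ko_P1CTL      = c(tumor_il27 = FALSE, tcell_il10 = FALSE),
  P1CTL_IL27        = c(tumor_il27 = TRUE,  tcell_il10 = TRUE),
  IL10ko_P1CTL_IL27 = c(tumor_il27 = TRUE,  tcell_il10 = FALSE))

.genotype_labels <- c(
  P1CTL = "P1CTL", IL10ko_P1CTL = "IL-10-/-P1CTL",
  P1CTL_IL27 = "P1CTL/IL-27", IL10ko_P1CTL_IL27 = "IL-10-/-P1CTL/IL-27")

# Self-consistent forward evaluation of the simplified (quasi-static,
# constant-source) models the estimation recipes invert, for one genotype
# arm between the two cell days.  Iterated to a fixed point so that every
# "constant source" equals the two-point average of the trajectory it
# generates; the estimators are then exact inverses on noiseless output.
simplified_arm <- function(p, T1, E1, tumor_il27, tcell_il10, t1, t2) {
  dt <- t2 - t1
  g <- p$lamT - p$d_T
  mu <- if (tumor_il27) p$mu1 else 0
  sat <- function(x, K) x / (K + x)
  I27_1 <- 0.8 * mu * T1 / p$d_I27
  I10_1 <- if (tcell_il10) {
    0.8 * (p$lam1 + p$lam2 * sat(I27_1, p$K_I27_10)) * E1 / p$d_I10
  } else 0
  G_1 <- 0.8 * p$lamG * E1 * p$K_I27_G / (p$K_I27_G + I27_1) / p$d_G
  T5 <- T1; E5 <- E1; I27_5 <- I27_1; I10_5 <- I10_1; G_5 <- G_1
  for (it in 1:500) {
    Tb <- (T1 + T5) / 2
    I27_5n <- lin_forward(I27_1, mu * Tb, p$d_I27, dt)
    I27b <- (I27_1 + I27_5n) / 2
    I10b <- (I10_1 + I10_5) / 2
    d_eff <- p$d_E / (1 + I27b / p$K_E1 + I10b / p$K_E2)
    A <- p$lamE * sat(Tb, p$K_T)
    E5n <- lin_forward(E1, A, d_eff, dt)
    Eb <- (E1 + E5n) / 2
    P10 <- if (tcell_il10) {
      (p$lam1 + p$lam2 * sat(I27b, p$K_I27_10)) * Eb
    } else 0
    I10_5n <- if (tcell_il10) lin_forward(I10_1, P10, p$d_I10, dt) else 0
    PG <- p$lamG * Eb * p$K_I27_G / (p$K_I27_G + I27b)
    G_5n <- lin_forward(G_1, PG, p$d_G, dt)
    Gb <- (G_1 + G_5n) / 2
    kill <- p$eta2 * sat(Gb, p$K_killG) +
      if (tcell_il10) p$eta1 * sat(I10b, p$K_kill10) else 0
    T5n <- T1 * exp((g - kill) * dt)
    delta <- max(abs(c(I27_5n - I27_5, E5n - E5, I10_5n - I10_5,
                       G_5n - G_5, T5n - T5)) /
                 pmax(abs(c(I27_5, E5, I10_5, G_5, T5)), 1e-300))
    I27_5 <- I27_5n; E5 <- E5n; I10_5 <- I10_5n; G_5 <- G_5n; T5 <- T5n
    if (delta < 1e-14) break
  }
  list(T = c(T1, T5), E = c(E1, E5), I27 = c(I27_1, I27_5),
       I10 = c(I10_1, I10_5), G = c(G_1, G_5))
}

#' Generate a synthetic observation set
#'
#' Produces the measurements the estimation cascade consumes: an exponential
#' tumor-volume series at the design's volume days and, for every requested
#' genotype arm, tumor/CTL densities and cytokine concentrations at the two
#' cell days.  Arm dynamics follow the simplified quasi-static models that
#' the closed-form estimators invert (evaluated to a self-consistent fixed
#' point), so at `cv = 0` the cascade recovers the generating parameters to
#' round-off.  Multiplicative lognormal noise (log-median preserving, CV as
#' designed) is applied to every reported value; all randomness flows
#' through the design seed.
#'
#' @param p generating [il27_parameters()].
#' @param design an [observation_design()].
#' @return An object of class `il27_observations`: list with
#'   `tumor_volume` (data frame `day`, `volume`), `arms` (per-genotype list
#'   of quantity matrices), `days`, `occupied_volume`, `design`, and the
#'   generating parameters as attribute `generator`.
#' @export
generate_observations <- function(p, design = observation_design()) {
  stopifnot(inherits(p, "il27_parameters"),
            inherits(design, "il27_obs_design"))
  set.seed(design$seed)
  sdlog <- sqrt(log(1 + design$cv^2))
  noisy <- function(x) {
    if (design$cv == 0) x else x * exp(stats::rnorm(length(x), 0, sdlog))
  }
  g <- p$lamT - p$d_T
  vol <- design$V1 * exp(g * (design$volume_days - design$volume_days[1]))
  vol <- noisy(vol)
  t1 <- design$cell_days[1]; t2 <- design$cell_days[2]
  arms <- lapply(design$genotypes, function(gt) {
    fl <- .genotype_flags[[gt]]
    a <- simplified_arm(p, design$T1, design$E1, fl[["tumor_il27"]],
                        fl[["tcell_il10"]], t1, t2)
    # only quantities that are physically present are reported
    if (!fl[["tumor_il27"]]) a$I27 <- NULL
    if (!fl[["tcell_il10"]]) a$I10 <- NULL
    lapply(a, noisy)
  })
  names(arms) <- design$genotypes
  structure(list(tumor_volume = data.frame(day = design$volume_days,
                                           volume = vol),
                 arms = arms, days = design$cell_days,
                 occupied_volume = design$occupied_volume,
                 design = design),
            class = "il27_observations", generator = p)
}

#' Look up one observed value
#'
#' @param obs an `il27_observations` object.
#' @param arm genotype arm name.
#' @param quantity one of `"T"`, `"E"`, `"I27"`, `"I10"`, `"G"`.
#' @param day one of the two cell days.
#' @return Scalar value (density or concentration).
#' @export
arm_value <- function(obs, arm, quantity, day) {
  stopifnot(inherits(obs, "il27_observations"))
  a <- obs$arms[[arm]]
  if (is.null(a)) stop("arm not observed: ", arm, call. = FALSE)
  q <- a[[quantity]]
  if (is.null(q)) stop("quantity ", quantity, " not observed in arm ", arm,
                       call. = FALSE)
  i <- match(day, obs$days)
  if (is.na(i)) stop("day ", day, " not a measurement day", call. = FALSE)
  q[i]
}

.quantity_units <- c(T = "cells/cm^3", E = "cells/cm^3", I27 = "pg/cm^3",
                     I10 = "pg/cm^3", G = "pg/cm^3")

#' Write an observation set as tidy CSV plus a JSON manifest
#'
#' The CSV has columns `arm, quantity, day, value, units` (tumor volumes use
#' arm `"volume_series"`); the manifest records the design and, for
#' synthetic sets, the generating parameters for recovery scoring.
#'
#' @param obs an `il27_observations` object.
#' @param path CSV output path; the manifest is written alongside with
#'   extension `.json`.
#' @return Named character vector of paths, invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "il27_observations"))
  rows <- data.frame(arm = "volume_series", quantity = "V",
                     day = obs$tumor_volume$day,
                     value = obs$tumor_volume$volume, units = "mm^3")
  for (arm in names(obs$arms)) {
    for (q in names(obs$arms[[arm]])) {
      rows <- rbind(rows, data.frame(arm = arm, quantity = q,
                                     day = obs$days,
                                     value = obs$arms[[arm]][[q]],
                                     units = .quantity_units[[q]]))
    }
  }
  utils::write.csv(rows, path, row.names = FALSE)
  mpath <- paste0(tools::file_path_sans_ext(path), ".json")
  gen <- attr(obs, "generator")
  manifest <- list(design = unclass(obs$design),
                   occupied_volume = obs$occupied_volume,
                   generator = if (!is.null(gen)) as.list(unclass(gen)))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = path, manifest = mpath))
}

#' Read an observation set written by [write_observations()]
#'
#' @param path CSV path (the JSON manifest is read from the same stem).
#' @return An `il27_observations` object.
#' @export
read_observations <- function(path) {
  rows <- utils::read.csv(path)
  mpath <- paste0(tools::file_path_sans_ext(path), ".json")
  manifest <- if (file.exists(mpath)) {
    jsonlite::read_json(mpath, simplifyVector = TRUE)
  }
  vol <- rows[rows$arm == "volume_series", ]
  cell <- rows[rows$arm != "volume_series", ]
  days <- sort(unique(cell$day))
  arms <- lapply(split(cell, cell$arm), function(df) {
    lapply(split(df, df$quantity),
           function(qq) qq$value[order(qq$day)])
  })
  design <- if (!is.null(manifest$design)) {
    do.call(observation_design, manifest$design[
      intersect(names(manifest$design), names(formals(observation_design)))])
  }
  gen <- if (!is.null(manifest$generator)) {
    do.call(il27_parameters,
            manifest$generator[names(manifest$generator) %in%
                               names(param_units())])
  }
  structure(list(tumor_volume = data.frame(day = vol$day,
                                           volume = vol$value),
                 arms = arms, days = days,
                 occupied_volume = manifest$occupied_volume %||% NA_real_,
                 design = design),
            class = "il27_observations", generator = gen)
}
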