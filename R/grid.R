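#' Uniform radial grid on a ball
#'
#' Builds `N + 1` equally spaced nodes `r_0 = 0, ..., r_N = R` together with
#' the finite-volume dual-cell shell volumes used for quadrature and for the
#' conservative spherical Laplacian.  Node `i` owns the shell between the
#' faces at `r_i - h/2` and `r_i + h/2` (clipped to `[0, R]`), so the shell
#' volumes telescope exactly to the ball volume `4/3 pi R^3`.
#'
#' @param R domain radius, cm.
#' @param N number of intervals (`N + 1` nodes); at least 8.
#' @return An object of class `il27_grid` with elements `r` (node radii),
#'   `h` (spacing), `R`, `N`, `volumes` (dual shell volumes) and
#'   `face_areas` (areas of the `N` interior faces at `r_{i+1/2}`).
#' @export
#' @examples
#' g <- build_grid(R = 1, N = 10)
#' sum(g$volumes) - 4 / 3 * pi     # ~ 0
build_grid <- function(R, N) {
  if (!is.finite(R) || R <= 0) stop("R must be positive", call. = FALSE)
  if (!is.finite(N) || N < 8) stop("N must be at least 8", call. = FALSE)
  N <- as.integer(N)
  h <- R / N
  r <- seq(0, R, length.out = N + 1)
  faces <- r[-length(r)] + h / 2          # interior faces r_{i+1/2}
  bounds <- c(0, faces, R)                # dual-cell boundaries
  volumes <- 4 / 3 * pi * diff(bounds^3)
  structure(list(r = r, h = h, R = R, N = N, volumes = volumes,
                 face_areas = 4 * pi * faces^2),
            class = "il27_grid")
}

#' Conservative spherical Laplacian with no-flux boundaries
#'
#' Finite-volume discretization of `(1/r^2) d/dr (r^2 df/dr)` on the dual
#' cells of an [build_grid()] grid.  The flux through the face at the origin
#' vanishes by symmetry (zero area) and the flux through `r = R` is set to
#' zero (no-flux/Neumann), so the volume-weighted sum of the result is zero
#' to round-off and diffusion conserves total amount exactly.
#'
#' @param f numeric vector of nodal values (length `N + 1`).
#' @param grid an `il27_grid`.
#' @return Numeric vector: the discrete Laplacian at each node.
#' @export
radial_laplacian <- function(f, grid) {
  stopifnot(inherits(grid, "il27_grid"))
  if (length(f) != grid$N + 1L)
    stop("field length (", length(f), ") does not match grid (",
         grid$N + 1L, " nodes)", call. = FALSE)
  flux <- grid$face_areas * diff(f) / grid$h  # A_{i+1/2} (f_{i+1}-f_i)/h
  (c(flux, 0) - c(0, flux)) / grid$volumes
}

#' Total amount of a species over the ball
#'
#' Shell-volume-weighted quadrature `4 pi int f(r) r^2 dr`; returns pg for
#' cytokines or cells for cell densities.
#'
#' @param f nodal values (length `N + 1`).
#' @param grid an `il27_grid`.
#' @return Scalar total.
#' @export
total_amount <- function(f, grid) {
  stopifnot(inherits(grid, "il27_grid"))
  if (length(f) != grid$N + 1L)
    stop("field length does not match grid", call. = FALSE)
  sum(grid$volumes * f)
}
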