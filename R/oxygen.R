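#' Oxygen physics parameters
#'
#' Fixed, cell-line independent oxygen physics: diffusion constant, surface
#' pressure, anoxic threshold and the per-cell-volume consumption rate. The
#' diffusion constant is supplied in SI (m^2/s) as usually reported and
#' converted once to the internal unit system (um, hours, mmHg); the
#' consumption rate is supplied in mmHg/s and converted to mmHg/h.
#'
#' @param a oxygen consumption rate in mmHg/s (per unit packed cell volume).
#' @param D_rho oxygen diffusion constant in m^2/s (default 2e-9).
#' @param rho0 oxygen pressure at the spheroid surface, mmHg (default 100).
#' @param rho_an anoxic threshold pressure, mmHg (default 0).
#' @return An object of class `physics_params` with the SI inputs and the
#'   converted internal fields `D_um2_h` (um^2/h) and `a_h` (mmHg/h).
#' @examples
#' ph <- physics_params(a = 27.7)
#' ph$D_um2_h  # 7.2e6 um^2/h
#' @export
physics_params <- function(a, D_rho = 2e-9, rho0 = 100, rho_an = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0,
            D_rho > 0, rho0 > rho_an, rho_an >= 0)
  ph <- list(a = a, D_rho = D_rho, rho0 = rho0, rho_an = rho_an,
             a_h = a * 3600, D_um2_h = D_rho * 1e12 * 3600)
  class(ph) <- "physics_params"
  ph
}

#' Surface shell of a spheroid
#'
#' The spheroid surface is the center of the outermost shell whose total cell
#' concentration exceeds 0.1; the constant-oxygen boundary condition is
#' applied there.
#'
#' @param state a [spheroid_state()].
#' @param grid the matching [shell_grid()].
#' @param threshold detection threshold on the total concentration.
#' @return A list with `surface_index` (0-based shell index) and
#'   `surface_radius` (um).
#' @export
find_surface_shell <- function(state, grid, threshold = 0.1) {
  tot <- rowSums(state$conc)
  idx <- which(tot > threshold)
  if (length(idx) == 0L)
    stop("empty spheroid: no shell has total concentration above ", threshold)
  i0 <- max(idx) - 1L
  list(surface_index = i0, surface_radius = grid$centers[i0 + 1L])
}

#' Quasi-steady-state radial oxygen profile
#'
#' Solves the steady state of the rotationally symmetric diffusion equation
#' `D 1/r^2 d/dr(r^2 drho/dr) = a * (c_p + c_d) * 1[rho > rho_an]` on the
#' shell centers, with Dirichlet `rho = rho0` at the surface shell and zero
#' flux at the center, using conservative finite volumes and a monotone
#' fixed-point iteration for the anoxic free boundary (consumption is switched
#' off, never on, where `rho <= rho_an`; the converged anoxic core is clamped
#' to `rho_an`). Both proliferation-competent and damaged cells consume;
#' membrane-defect cells do not. Shells outside the surface are fully
#' oxygenated at `rho0`.
#'
#' @param state a [spheroid_state()].
#' @param grid the matching [shell_grid()].
#' @param physics a [physics_params()].
#' @param max_iter cap on free-boundary iterations (default 100).
#' @return An object of class `oxygen_profile`: list with `rho` (mmHg per
#'   shell), `consuming` (logical per shell), `surface_index`,
#'   `surface_radius` (um), `anoxic_radius` (um; the center of the outermost
#'   anoxic shell, the unbiased discrete estimate of the free boundary; 0 if
#'   there is no anoxic core) and the discrete balance diagnostics
#'   `consumption_total` and `surface_influx`.
#' @export
solve_oxygen <- function(state, grid, physics, max_iter = 100L) {
  stopifnot(inherits(physics, "physics_params"))
  surf <- find_surface_shell(state, grid)
  cons <- state$conc[, "p"] + state$conc[, "d"]
  res <- cpp_solve_oxygen(cons, surf$surface_index, grid$dr, physics$D_um2_h,
                          physics$rho0, physics$rho_an, physics$a_h,
                          as.integer(max_iter))
  out <- list(rho = res$rho, consuming = res$consuming,
              surface_index = surf$surface_index,
              surface_radius = surf$surface_radius,
              anoxic_radius = res$r_an, iterations = res$iterations,
              consumption_total = res$consumption_total,
              surface_influx = res$surface_influx)
  class(out) <- "oxygen_profile"
  out
}

#' @export
print.oxygen_profile <- function(x, ...) {
  cat(sprintf(
    "<oxygen_profile> surface r0 = %.4g um, anoxic r_an = %.4g um, %d shells\n",
    x$surface_radius, x$anoxic_radius, length(x$rho)))
  invisible(x)
}

#' Largest fully oxygenated spheroid radius
#'
#' For a uniformly dense spheroid the steady-state center pressure reaches the
#' anoxic threshold at `r_lim = sqrt(6 D (rho0 - rho_an) / a)`; larger
#' spheroids develop an anoxic core.
#'
#' @param physics a [physics_params()] with `a > 0`.
#' @return The oxygenation limit radius in micrometers.
#' @examples
#' oxygenation_limit_radius(physics_params(a = 27.7))  # ~208 um
#' @export
oxygenation_limit_radius <- function(physics) {
  stopifnot(inherits(physics, "physics_params"))
  if (physics$a_h <= 0)
    stop("oxygenation limit undefined for zero consumption rate")
  sqrt(6 * physics$D_um2_h * (physics$rho0 - physics$rho_an) / physics$a_h)
}

#' Necrotic radius implied by an outer radius
#'
#' For a uniformly consuming shell `r_n <= r <= r_o` with zero flux and
#' `rho = rho_an` at the anoxic boundary `r_n`, the steady-state profile gives
#' the closed-form relation
#' `rho0 - rho_an = a/(6 D) * (r_o^2 + 2 r_n^3 / r_o - 3 r_n^2)`.
#' This function returns its root `r_n` (0 if `r_outer` is below the
#' oxygenation limit), found by bracketed root-finding to 1e-3 um. It is the
#' inversion used to infer necrotic radii from measured outer radii.
#'
#' @param r_outer outer radius in um (may be a vector).
#' @param physics a [physics_params()] with `a > 0`.
#' @return Necrotic radius (um), same length as `r_outer`.
#' @export
necrotic_from_outer <- function(r_outer, physics) {
  stopifnot(inherits(physics, "physics_params"), all(r_outer > 0))
  if (physics$a_h <= 0) return(rep(0, length(r_outer)))
  rlim <- oxygenation_limit_radius(physics)
  drop_target <- physics$rho0 - physics$rho_an
  coef <- physics$a_h / (6 * physics$D_um2_h)
  vapply(r_outer, function(ro) {
    if (ro <= rlim) return(0)
    f <- function(rn) drop_target - coef * (ro^2 + 2 * rn^3 / ro - 3 * rn^2)
    # f(0) < 0 for ro > rlim, f(ro) = drop_target > 0: bracketed
    stats::uniroot(f, c(0, ro), tol = 1e-3)$root
  }, numeric(1))
}

#' Infer the necrotic-radius curve from a growth curve
#'
#' Applies [necrotic_from_outer()] pointwise to the outer radii of a growth
#' curve, mirroring the use of the closed-form oxygen relation to estimate
#' secondary necrotic radii when histological sections are unavailable.
#'
#' @param curve a [growth_curve()].
#' @param physics a [physics_params()].
#' @return The curve with its `necrotic_radius_um` column (re)computed.
#' @export
infer_necrotic_curve <- function(curve, physics) {
  stopifnot(inherits(curve, "growth_curve"))
  curve$necrotic_radius_um <- necrotic_from_outer(curve$radius_um, physics)
  curve
}
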