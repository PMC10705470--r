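#' Growth curve container
#'
#' Times in days with outer radii in micrometers, optionally with necrotic
#' radii. This is the tabular object read from and written to CSV and the
#' target of calibration.
#'
#' @param time_d strictly increasing times, days.
#' @param radius_um outer radii, um.
#' @param necrotic_radius_um optional necrotic radii, um.
#' @return A data frame of class `growth_curve`.
#' @export
growth_curve <- function(time_d, radius_um, necrotic_radius_um = NULL) {
  if (length(time_d) != length(radius_um))
    stop("time and radius must have the same length")
  if (any(diff(time_d) <= 0)) stop("times must be strictly increasing")
  if (any(radius_um < 0)) stop("radii must be non-negative")
  gc <- data.frame(time_d = time_d, radius_um = radius_um)
  if (!is.null(necrotic_radius_um)) {
    if (length(necrotic_radius_um) != length(time_d))
      stop("necrotic radii must match times")
    if (any(necrotic_radius_um < 0)) stop("radii must be non-negative")
    gc$necrotic_radius_um <- necrotic_radius_um
  }
  class(gc) <- c("growth_curve", "data.frame")
  gc
}

#' Volume-equivalent outer radius of a state
#'
#' Radius of the sphere whose volume equals the total cell volume
#' `sum_i V_i sum_T c_T(r_i)` over all three types.
#'
#' @param state a [spheroid_state()].
#' @param grid the matching [shell_grid()].
#' @return Radius in micrometers (0 for an empty state).
#' @export
spheroid_radius <- function(state, grid) {
  V <- sum(grid$volumes * rowSums(state$conc))
  (3 * V / (4 * pi))^(1 / 3)
}

#' Volume-equivalent necrotic radius of a state
#'
#' As [spheroid_radius()] but counting only membrane-defect (`n`) volume.
#'
#' @inheritParams spheroid_radius
#' @return Radius in micrometers (0 if there are no `n` cells).
#' @export
necrotic_radius <- function(state, grid) {
  V <- sum(grid$volumes * state$conc[, "n"])
  (3 * V / (4 * pi))^(1 / 3)
}

#' Trajectory as a growth curve
#'
#' @param traj an `rs_trajectory` from [simulate_spheroid()].
#' @return A [growth_curve()] (time converted from hours to days).
#' @export
as_growth_curve <- function(traj) {
  stopifnot(inherits(traj, "rs_trajectory"))
  s <- traj$summary
  growth_curve(s$time_h / 24, s$R_spheroid_um, s$R_necrotic_um)
}

#' Coefficient of determination on spheroid volumes
#'
#' `R^2 = 1 - sum((Vhat_k - V_k)^2) / sum((Vhat_k - mean(Vhat))^2)` where
#' `Vhat` are the data volumes `4/3 pi Rhat^3` and `V` the model volumes
#' linearly interpolated to the data times. Goodness of fit is conventionally
#' reported on volumes even when residuals are minimized on radii.
#'
#' @param model a [growth_curve()] densely sampled from the model.
#' @param data a [growth_curve()] of measurements (>= 3 points).
#' @return Dimensionless R^2 (1 for a perfect match, 0 for the data mean).
#' @export
r_squared_volume <- function(model, data) {
  stopifnot(inherits(model, "growth_curve"), inherits(data, "growth_curve"))
  if (nrow(data) < 3) stop("need at least 3 data points for R^2")
  vol <- function(r) 4 / 3 * pi * r^3
  vm <- stats::approx(model$time_d, vol(model$radius_um), xout = data$time_d,
                      rule = 2)$y
  vd <- vol(data$radius_um)
  1 - sum((vd - vm)^2) / sum((vd - mean(vd))^2)
}

#' Growth-regime diagnostics of a trajectory
#'
#' Spheroid growth is exponential while the radius is below the interaction
#' range `dr` (every cell can proliferate) and asymptotically linear above
#' about `3 dr` (only an outer rim proliferates, slope set by the product
#' `gamma * dr`). Reports the late-time linear slope (least-squares line over
#' the last quarter of samples), the early exponential rate of the total
#' volume (fit where `R < dr`), and the predicted transition window
#' `[dr, 3 dr] = [kappa dr_star, 3 kappa dr_star]`.
#'
#' @param traj an `rs_trajectory`.
#' @param params the [model_params()] used for the run.
#' @return List with `late_slope_um_h` (and its window), `early_exp_rate_h`
#'   (and the number of points used; `NA` with a flag if the trajectory never
#'   has `R < dr`), and `transition_window_um`.
#' @export
regime_diagnostics <- function(traj, params) {
  stopifnot(inherits(traj, "rs_trajectory"), inherits(params, "rs_params"))
  s <- traj$summary
  dr <- params$dr
  n <- nrow(s)
  i_late <- seq.int(max(1L, ceiling(0.75 * n)), n)
  late <- if (length(i_late) >= 2) {
    unname(coef(lm(R_spheroid_um ~ time_h, data = s[i_late, ]))[2])
  } else NA_real_
  i_small <- which(s$R_spheroid_um < dr & s$V_total_um3 > 0)
  early <- NA_real_
  early_reliable <- FALSE
  if (length(i_small) >= 3) {
    early <- unname(coef(lm(log(V_total_um3) ~ time_h,
                            data = s[i_small, ]))[2])
    early_reliable <- TRUE
  }
  list(late_slope_um_h = late,
       late_window_h = range(s$time_h[i_late]),
       early_exp_rate_h = early,
       early_points = length(i_small),
       early_reliable = early_reliable,
       transition_window_um = c(dr, 3 * dr))
}
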