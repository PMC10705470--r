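#' Radial-shell model parameters
#'
#' Collects the rate and physics constants of the radial-shell dynamics. The
#' shell width is tied to the single-cell diameter via `dr = kappa * dr_star`;
#' `kappa` is the effective range of proliferation in cell diameters and is
#' the quantity transferred to a cellular automaton neighborhood.
#'
#' @param gamma maximal proliferation rate, 1/h.
#' @param a oxygen consumption rate, mmHg/s (see [physics_params()]).
#' @param epsilon anoxic death rate, 1/h.
#' @param delta necrotic volume reduction rate, 1/h.
#' @param lambda inward transport rate, 1/h.
#' @param kappa shell width in cell diameters (>= 1).
#' @param dr_star single-cell diameter, um (default 16).
#' @param rho_h hypoxic proliferation threshold, mmHg; defaults to `rho_an`
#'   (proliferation inhibited only where cells are already anoxic).
#' @param D_rho,rho0,rho_an oxygen physics, passed to [physics_params()].
#' @param mc_loss_gated if `TRUE` (default) damaged-cell breakup occurs only
#'   where divisions are possible (`rho > rho_h`); if `FALSE` it applies
#'   everywhere, analogous to necrotic decay.
#' @param eps_on_damaged if `TRUE` (default) anoxic death also converts
#'   damaged cells to membrane-defect cells.
#' @param gate_width width (mmHg) of the smooth shoulder replacing the hard
#'   oxygen indicators in the dynamics (anoxic death
#'   `epsilon * exp(-(rho - rho_an)/width)`, proliferation
#'   `gamma * (1 - exp(-(rho - rho_h)/width))`). The default 0.5 mmHg blurs
#'   the anoxic boundary by well under a shell width while removing the
#'   free-boundary discontinuity that would otherwise stall the adaptive
#'   integrator; 0 gives the exact indicator forms.
#' @return An object of class `rs_params`.
#' @export
model_params <- function(gamma, a, epsilon, delta, lambda, kappa,
                         dr_star = 16, rho_h = NULL, D_rho = 2e-9,
                         rho0 = 100, rho_an = 0, mc_loss_gated = TRUE,
                         eps_on_damaged = TRUE, gate_width = 0.5) {
  physics <- physics_params(a = a, D_rho = D_rho, rho0 = rho0, rho_an = rho_an)
  if (is.null(rho_h)) rho_h <- rho_an
  stopifnot(gamma >= 0, epsilon >= 0, delta >= 0, lambda >= 0,
            kappa >= 1, dr_star > 0, rho_h >= rho_an, gate_width >= 0)
  p <- list(gamma = gamma, epsilon = epsilon, delta = delta, lambda = lambda,
            kappa = kappa, dr_star = dr_star, dr = kappa * dr_star,
            rho_h = rho_h, physics = physics, gate_width = gate_width,
            mc_loss_gated = isTRUE(mc_loss_gated),
            eps_on_damaged = isTRUE(eps_on_damaged))
  class(p) <- "rs_params"
  p
}

#' @export
print.rs_params <- function(x, ...) {
  cat(sprintf(
    paste0("<rs_params> gamma=%.4g/h (doubling %.3g h), a=%.4g mmHg/s,\n",
           "  epsilon=%.3g/h, delta=%.3g/h, lambda=%.3g/h (lambda*dr=%.3g um/h),\n",
           "  kappa=%.3g, dr=%.4g um, rho_h=%.3g mmHg\n"),
    x$gamma, log(2) / x$gamma, x$physics$a, x$epsilon, x$delta, x$lambda,
    x$lambda * x$dr, x$kappa, x$dr, x$rho_h))
  invisible(x)
}

# parameter list handed to the C++ core (internal)
cpp_pars <- function(params, oxy_max_iter = 100L) {
  list(gamma = params$gamma, a_h = params$physics$a_h,
       epsilon = params$epsilon, delta = params$delta,
       lambda = params$lambda, rho_h = params$rho_h,
       rho_an = params$physics$rho_an, rho0 = params$physics$rho0,
       D_um2_h = params$physics$D_um2_h, dr = params$dr,
       gate_width = params$gate_width,
       mc_loss_gated = params$mc_loss_gated,
       eps_on_damaged = params$eps_on_damaged,
       oxy_max_iter = as.integer(oxy_max_iter))
}

# neutral radiation parameters for untreated simulations (internal)
null_radiation <- function() {
  list(alpha = 0, beta = 0, oer_m = 3, oer_K = 3.28, Pmc1 = 0, Pmc2 = 1,
       tau_mc = 120, events = matrix(numeric(0), 0, 2))
}

#' Integrator and solver controls
#'
#' @param rtol,atol relative/absolute tolerance of the embedded Runge-Kutta
#'   pair (Dormand-Prince 5(4)).
#' @param h_init,h_min initial and minimal step size, hours.
#' @param clip_tol concentrations may transiently leave `[0, 1]` by at most
#'   this much; a step violating it is rejected and halved.
#' @param extend_threshold,extend_chunk outermost-shell occupancy that
#'   triggers grid growth, and the number of shells appended.
#' @param max_steps hard cap on integration steps.
#' @param record_profiles store full radial concentration and oxygen
#'   snapshots at every sample time.
#' @param oxy_max_iter cap on oxygen free-boundary iterations.
#' @return A list of control settings.
#' @export
rs_control <- function(rtol = 1e-6, atol = 1e-9, h_init = 0.1, h_min = 1e-10,
                       clip_tol = 1e-9, extend_threshold = 1e-6,
                       extend_chunk = 8L, max_steps = 5e6,
                       record_profiles = FALSE, oxy_max_iter = 100L) {
  list(rtol = rtol, atol = atol, h_init = h_init, h_min = h_min,
       clip_tol = clip_tol, extend_threshold = extend_threshold,
       extend_chunk = as.integer(extend_chunk), max_steps = max_steps,
       record_profiles = record_profiles,
       oxy_max_iter = as.integer(oxy_max_iter))
}

# assemble per-shell volume-rate terms (internal shared path)
rs_terms <- function(state, grid, rho, params, Pmc) {
  stopifnot(inherits(params, "rs_params"))
  if (inherits(rho, "oxygen_profile")) rho <- rho$rho
  cpp_rs_terms(state$conc, rho, cpp_pars(params), Pmc)
}

#' Proliferation volume rates
#'
#' Offspring volume produced in shell `i` at rate `gamma * c * V_i` (for
#' damaged cells, `gamma * (1 - Pmc) * c_d * V_i`) is placed into the
#' neighborhood `{i-1, i, i+1}` proportional to the local free volume
#' `F_j = (1 - sum_T c_T) V_j`, normalised by the neighborhood volume
#' `sum V_j` - free-space-proportional placement with a logistic cap. Shells
#' at or below the hypoxic threshold `rho_h` neither produce nor lose volume;
#' damaged cells additionally lose volume at rate `gamma * Pmc * c_d * V_i`
#' (mitotic catastrophe at division).
#'
#' @param state a [spheroid_state()].
#' @param grid the matching [shell_grid()].
#' @param rho an [solve_oxygen()] profile (or its `rho` vector).
#' @param params an [model_params()] object.
#' @param Pmc probability of mitotic catastrophe in `[0, 1]`.
#' @return List of per-shell volume rates (um^3/h): `gain_p`, `gain_d`,
#'   `loss_d`.
#' @export
proliferation_terms <- function(state, grid, rho, params, Pmc = 0) {
  stopifnot(Pmc >= 0, Pmc <= 1)
  t <- rs_terms(state, grid, rho, params, Pmc)
  list(gain_p = t$prolif_gain_p, gain_d = t$prolif_gain_d,
       loss_d = t$mc_loss_d)
}

#' Anoxic death and necrotic decay volume rates
#'
#' In shells with `rho <= rho_an`, proliferation-competent (and, by default,
#' damaged) cell volume converts to membrane-defect volume at rate `epsilon`;
#' everywhere, membrane-defect volume is lost at rate `delta`.
#'
#' @inheritParams proliferation_terms
#' @return List of per-shell volume rates (um^3/h): `conv_p_to_n`,
#'   `conv_d_to_n`, `decay_n`.
#' @export
death_decay_terms <- function(state, grid, rho, params) {
  t <- rs_terms(state, grid, rho, params, Pmc = 0)
  list(conv_p_to_n = t$conv_p_to_n, conv_d_to_n = t$conv_d_to_n,
       decay_n = t$decay_n)
}

#' Inward transport volume fluxes
#'
#' Between each shell pair `(i-1, i)` the total inward volume flux is
#' `lambda * (sum_T c_T(r_i)) * F_{i-1}`, apportioned across types by the
#' composition of shell `i`; the flux vanishes when the inner shell is full,
#' which keeps a packed core stationary and the spheroid compact.
#'
#' @inheritParams proliferation_terms
#' @return List of per-shell net volume rates (um^3/h): `p`, `d`, `n`.
#' @export
transport_terms <- function(state, grid, params) {
  rho <- rep(params$physics$rho0, grid$n_shells)  # transport is oxygen-blind
  t <- rs_terms(state, grid, rho, params, Pmc = 0)
  list(p = t$transport_p, d = t$transport_d, n = t$transport_n)
}

#' Time derivative of a spheroid state
#'
#' Recomputes the quasi-steady-state oxygen profile, assembles proliferation,
#' death/decay and transport volume rates and converts them to concentration
#' rates by dividing by the shell volumes.
#'
#' @param state a [spheroid_state()].
#' @param grid the matching [shell_grid()].
#' @param params an [model_params()] object.
#' @param Pmc probability of mitotic catastrophe (relevant once damaged cells
#'   exist).
#' @return List with `dconc` (n x 3 matrix of d(conc)/dt, 1/h) and `rho`
#'   (the oxygen profile used).
#' @export
rs_rhs <- function(state, grid, params, Pmc = 0) {
  stopifnot(inherits(params, "rs_params"))
  cpp_rs_rhs(state$conc, cpp_pars(params), Pmc)
}

#' Simulate radial-shell spheroid dynamics
#'
#' Integrates the model with an embedded adaptive Dormand-Prince 5(4) scheme.
#' Irradiation events are applied instantaneously at their times (hard
#' breakpoints), the grid auto-extends so the spheroid never reaches the
#' boundary, and no concentration leaves `[0, 1]` at accepted steps.
#'
#' @param state initial [spheroid_state()].
#' @param grid the matching [shell_grid()].
#' @param params an [model_params()] object.
#' @param t_end simulation horizon in hours (from `state$time`).
#' @param rad a [radiation_params()] object, or `NULL` for untreated growth.
#'   Its `events` (time in hours, dose in Gy) are applied during the run.
#' @param sample_every sampling cadence in hours (default 24).
#' @param sample_times explicit absolute sample times (hours), overriding
#'   `sample_every`.
#' @param control see [rs_control()].
#' @return An object of class `rs_trajectory`: list with `summary` (data frame
#'   `time_h`, `R_spheroid_um`, `R_necrotic_um`, `V_total_um3`, `V_p`, `V_d`,
#'   `V_n`), `profiles` (if recorded), the final `state` and `grid`, `params`
#'   and integrator diagnostics.
#' @export
simulate_spheroid <- function(state, grid, params, t_end, rad = NULL,
                              sample_every = 24, sample_times = NULL,
                              control = rs_control()) {
  stopifnot(inherits(state, "spheroid_state"), inherits(grid, "shell_grid"),
            inherits(params, "rs_params"), t_end > 0)
  validate_state(state, grid)
  t0 <- state$time
  tf <- t0 + t_end
  if (is.null(sample_times))
    sample_times <- unique(c(seq(t0, tf, by = sample_every), tf))
  sample_times <- sort(sample_times)
  rl <- if (is.null(rad)) null_radiation() else unclass(rad)
  ev <- rl$events
  if (is.data.frame(ev)) ev <- as.matrix(ev)
  if (is.null(ev) || length(ev) == 0) ev <- matrix(numeric(0), 0, 2)
  res <- cpp_simulate(state$conc, t0, cpp_pars(params, control$oxy_max_iter),
                      rl, ev, sample_times, tf, NA_real_,
                      if (is.null(attr(state, "last_irr"))) -Inf
                      else attr(state, "last_irr"),
                      control)
  if (!res$status %in% c("ok", "stopped"))
    stop("integration failed: ", res$status,
         " (t = ", format(res$t_final), " h)")
  as_trajectory(res, grid, params)
}

# wrap a cpp_simulate result (internal)
as_trajectory <- function(res, grid, params) {
  grid2 <- shell_grid(grid$dr, res$n_shells)
  fin <- list(time = res$t_final, conc = res$conc_final)
  class(fin) <- "spheroid_state"
  attr(fin, "last_irr") <- res$last_irr
  traj <- list(
    summary = data.frame(time_h = res$time, R_spheroid_um = res$R,
                         R_necrotic_um = res$Rn,
                         V_total_um3 = res$Vp + res$Vd + res$Vn,
                         V_p = res$Vp, V_d = res$Vd, V_n = res$Vn),
    profiles = if (length(res$conc_snapshots)) {
      list(conc = res$conc_snapshots, rho = res$rho_snapshots)
    },
    state = fin, grid = grid2, params = params,
    diagnostics = list(status = res$status, n_accept = res$n_accept,
                       n_reject = res$n_reject, stop_time = res$stop_time))
  class(traj) <- "rs_trajectory"
  traj
}

#' @export
print.rs_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rs_trajectory> %d samples over t = [%.4g, %.4g] h; R: %.4g -> %.4g um\n",
    nrow(s), min(s$time_h), max(s$time_h), s$R_spheroid_um[1],
    s$R_spheroid_um[nrow(s)]))
  invisible(x)
}

#' @export
as.data.frame.rs_trajectory <- function(x, ...) x$summary
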