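#' Radiotherapy parameters
#'
#' Linear-quadratic radiosensitivities, the Alper-Howard-Flanders oxygen
#' enhancement constants, the two-level mitotic-catastrophe schedule and the
#' irradiation event list.
#'
#' @param alpha,beta LQ coefficients (1/Gy, 1/Gy^2).
#' @param Pmc1 initial probability of mitotic catastrophe (< 0.5).
#' @param Pmc2 late probability of mitotic catastrophe (> 0.5).
#' @param tau_mc delay after irradiation at which `Pmc` switches from `Pmc1`
#'   to `Pmc2`, hours (default 120).
#' @param oer_m maximal oxygen enhancement ratio (default 3).
#' @param oer_K half-effect oxygen pressure, mmHg (default 3.28).
#' @param events irradiation schedule: data frame or matrix with columns
#'   `time_h` and `dose_Gy` (multiple rows allow fractionation).
#' @return An object of class `radiation_params`.
#' @export
radiation_params <- function(alpha, beta, Pmc1, Pmc2, tau_mc = 120,
                             oer_m = 3, oer_K = 3.28,
                             events = data.frame(time_h = numeric(0),
                                                 dose_Gy = numeric(0))) {
  stopifnot(alpha >= 0, beta >= 0, oer_m >= 1, oer_K > 0,
            Pmc1 >= 0, Pmc1 < 0.5, Pmc2 > 0.5, Pmc2 <= 1, tau_mc >= 0)
  ev <- as.data.frame(events)
  if (nrow(ev) && !all(c("time_h", "dose_Gy") %in% names(ev)))
    stop("`events` needs columns time_h and dose_Gy")
  if (nrow(ev) && any(ev$dose_Gy < 0)) stop("doses must be non-negative")
  r <- list(alpha = alpha, beta = beta, oer_m = oer_m, oer_K = oer_K,
            Pmc1 = Pmc1, Pmc2 = Pmc2, tau_mc = tau_mc,
            events = if (nrow(ev)) as.matrix(ev[order(ev$time_h), ])
                     else matrix(numeric(0), 0, 2))
  class(r) <- "radiation_params"
  r
}

#' @export
print.radiation_params <- function(x, ...) {
  cat(sprintf(
    "<radiation_params> alpha=%.3g/Gy beta=%.3g/Gy^2 OER(m=%.3g, K=%.3g mmHg)\n  Pmc: %.3g -> %.3g at %g h; %d event(s)\n",
    x$alpha, x$beta, x$oer_m, x$oer_K, x$Pmc1, x$Pmc2, x$tau_mc,
    nrow(x$events)))
  invisible(x)
}

#' Oxygen-dependent effective dose
#'
#' The Alper-Howard-Flanders oxygen equation reduces the physical dose `d` to
#' an effective dose `d_eff = d (m rho + K) / (m (rho + K))`, so the oxygen
#' enhancement ratio `d / d_eff` falls from `m` under anoxia to 1 at full
#' oxygenation.
#'
#' @param d physical dose, Gy (vectorized).
#' @param rho local oxygen pressure, mmHg (vectorized).
#' @param rad a [radiation_params()] object.
#' @return Effective dose in Gy, `<= d`.
#' @export
effective_dose <- function(d, rho, rad) {
  stopifnot(all(d >= 0), all(rho >= 0))
  d * (rad$oer_m * rho + rad$oer_K) / (rad$oer_m * (rho + rad$oer_K))
}

#' Linear-quadratic survival probability
#'
#' `S = exp(-(alpha d_eff + beta d_eff^2))`, the canonical LQ model.
#'
#' @param d_eff effective dose, Gy (vectorized).
#' @param rad a [radiation_params()] object.
#' @return Survival probability in `(0, 1]`.
#' @export
lq_survival <- function(d_eff, rad) {
  stopifnot(all(d_eff >= 0))
  exp(-(rad$alpha * d_eff + rad$beta * d_eff^2))
}

#' Apply an instantaneous irradiation to a state
#'
#' Per shell, the fraction `1 - S(d_eff(dose, rho))` of proliferation-
#' competent cells is converted to damaged cells; membrane-defect cells and
#' the per-shell total concentration are unchanged.
#'
#' @param state a [spheroid_state()].
#' @param grid the matching [shell_grid()].
#' @param rho an [solve_oxygen()] profile (or plain vector of mmHg values).
#' @param dose physical dose in Gy.
#' @param rad a [radiation_params()] object.
#' @return The post-irradiation [spheroid_state()]; the event time is stored
#'   so a following [simulate_spheroid()] applies the mitotic-catastrophe
#'   clock correctly.
#' @export
irradiate <- function(state, grid, rho, dose, rad) {
  stopifnot(inherits(state, "spheroid_state"), dose >= 0)
  if (inherits(rho, "oxygen_profile")) rho <- rho$rho
  stopifnot(length(rho) == nrow(state$conc))
  out <- state
  out$conc <- cpp_irradiate(state$conc, rho, dose, rad$alpha, rad$beta,
                            rad$oer_m, rad$oer_K)
  attr(out, "last_irr") <- state$time
  out
}

#' Mitotic-catastrophe probability after irradiation
#'
#' Step schedule: `Pmc1` before the switch delay `tau_mc`, `Pmc2` afterwards.
#'
#' @param t_since_irradiation time since the (most recent) irradiation, hours.
#' @param rad a [radiation_params()] object.
#' @return Probability of mitotic catastrophe at division.
#' @export
pmc_at <- function(t_since_irradiation, rad) {
  stopifnot(all(t_since_irradiation >= 0))
  ifelse(t_since_irradiation < rad$tau_mc, rad$Pmc1, rad$Pmc2)
}
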