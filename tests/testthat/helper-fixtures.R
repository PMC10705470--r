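# shared fixtures: literature-flavored parameter sets and small states

hct116_params <- function(...) {
  model_params(gamma = log(2) / 22.8, a = 27.7, epsilon = 0.23,
               delta = 0.0111, lambda = 38.8 / (1.12 * 16), kappa = 1.12, ...)
}

fadu_params <- function(...) {
  model_params(gamma = log(2) / 36, a = 9.9, epsilon = 0.36, delta = 0.031,
               lambda = 53.3 / (4.15 * 16), kappa = 4.15, ...)
}

hct116_rad <- function(events = data.frame(time_h = numeric(0),
                                           dose_Gy = numeric(0)), ...) {
  radiation_params(alpha = 0.5, beta = 0.042, Pmc1 = 0.27, Pmc2 = 0.67,
                   events = events, ...)
}

# uniformly packed ball of p cells with the exact target volume
uniform_ball <- function(R, grid) {
  k <- floor(R / grid$dr)
  cp <- rep(0, grid$n_shells)
  if (k > 0) cp[seq_len(k)] <- 1
  cp[k + 1] <- (4 / 3 * pi * R^3 - sum(grid$volumes[seq_len(k)])) /
    grid$volumes[k + 1]
  spheroid_state(grid, p = cp)
}

# late-time slope of the outer radius (least squares on the last quarter)
late_slope <- function(traj) {
  s <- traj$summary
  n <- nrow(s)
  i <- seq.int(ceiling(0.75 * n), n)
  unname(coef(lm(R_spheroid_um ~ time_h, data = s[i, ]))[2])
}
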