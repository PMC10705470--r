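# term-level tests use gate_width = 0 (exact indicator gating)

test_that("proliferation follows free-space-proportional placement", {
  p <- model_params(gamma = 0.04, a = 0, epsilon = 0, delta = 0, lambda = 0,
                    kappa = 1, gate_width = 0)
  g <- shell_grid(16, 3)
  st <- spheroid_state(g, p = c(0.8, 0.5, 0))
  rho <- rep(100, 3)
  tm <- proliferation_terms(st, g, rho, p)
  V <- g$volumes
  FF <- (1 - rowSums(st$conc)) * V
  # source shell 1 (middle): hand evaluation of gamma*c*V1*F_j/sum(V)
  from1 <- 0.04 * 0.5 * V[2] * FF / sum(V)
  # source shell 0: neighborhood {0, 1}
  from0 <- 0.04 * 0.8 * V[1] * FF[1:2] / sum(V[1:2])
  expect_equal(tm$gain_p, from1 + c(from0, 0), tolerance = 1e-12)
  expect_equal(tm$loss_d, rep(0, 3))
  # fully packed neighborhood: logistic cap, zero production
  stf <- spheroid_state(g, p = 1)
  expect_equal(proliferation_terms(stf, g, rho, p)$gain_p, rep(0, 3))
  # dilute limit: total production approaches gamma * c * V
  std <- spheroid_state(g, p = c(1e-3, 0, 0))
  tot <- sum(proliferation_terms(std, g, rho, p)$gain_p)
  expect_equal(tot, 0.04 * 1e-3 * V[1], tolerance = 2e-3)
  # hypoxic shells produce nothing
  expect_equal(proliferation_terms(st, g, c(0, 0, 100), p)$gain_p[1], 0)
})

test_that("damaged cells with Pmc = 1 only lose volume at divisions", {
  p <- model_params(gamma = 0.03, a = 0, epsilon = 0, delta = 0, lambda = 0,
                    kappa = 1, gate_width = 0)
  g <- shell_grid(16, 4)
  st <- spheroid_state(g, d = c(0.5, 0.2, 0, 0))
  attr(st, "last_irr") <- 0
  rad <- radiation_params(alpha = 0.5, beta = 0.042, Pmc1 = 0.27, Pmc2 = 1,
                          tau_mc = 0)
  tr <- simulate_spheroid(st, g, p, t_end = 50, rad = rad, sample_every = 5)
  s <- tr$summary
  rate <- unname(coef(lm(log(V_d) ~ time_h, data = s))[2])
  expect_equal(rate, -p$gamma, tolerance = 1e-3)
  expect_true(all(s$V_p == 0))
})

test_that("anoxic death and necrotic decay solve the two-compartment ODE", {
  # shells 0-1 occupied; huge consumption makes shell 0 anoxic throughout
  p <- model_params(gamma = 0, a = 2770, epsilon = 0.3, delta = 0.05,
                    lambda = 0, kappa = 1, rho_an = 99, gate_width = 0)
  g <- shell_grid(16, 4)
  st <- spheroid_state(g, p = c(1, 1, 0, 0))
  ox <- solve_oxygen(st, g, p$physics)
  expect_lte(ox$rho[1], 99)  # inner shell anoxic, surface shell Dirichlet
  tt <- seq(0, 10, by = 2)
  tr <- simulate_spheroid(st, g, p, t_end = 10, sample_times = tt,
                          control = rs_control(record_profiles = TRUE))
  cp <- vapply(tr$profiles$conc, function(m) m[1, "p"], numeric(1))
  cn <- vapply(tr$profiles$conc, function(m) m[1, "n"], numeric(1))
  expect_equal(cp, exp(-0.3 * tt), tolerance = 1e-5)
  expect_equal(cn, 0.3 / (0.3 - 0.05) * (exp(-0.05 * tt) - exp(-0.3 * tt)),
               tolerance = 1e-4)
  # no anoxic shell: only delta-decay of existing n
  p2 <- model_params(gamma = 0, a = 0, epsilon = 0.3, delta = 0.05,
                     lambda = 0, kappa = 1, gate_width = 0)
  d2 <- death_decay_terms(spheroid_state(g, p = 0.5, n = 0.2), g,
                          rep(100, 4), p2)
  expect_equal(d2$conv_p_to_n, rep(0, 4))
  expect_equal(d2$decay_n, 0.05 * 0.2 * g$volumes)
})

test_that("inward transport is compact and volume-conservative", {
  p <- model_params(gamma = 0, a = 0, epsilon = 0, delta = 0, lambda = 2,
                    kappa = 1, gate_width = 0)
  g <- shell_grid(16, 2)
  st <- spheroid_state(g, p = c(0.3, 0.5))
  tt <- transport_terms(st, g, p)
  J <- 2 * 0.5 * (1 - 0.3) * g$volumes[1]
  expect_equal(tt$p, c(J, -J), tolerance = 1e-12)
  expect_equal(sum(tt$p) + sum(tt$d) + sum(tt$n), 0)
  # full inner shell: packed core is stationary
  stf <- spheroid_state(g, p = c(1, 0.5))
  expect_equal(transport_terms(stf, g, p)$p, c(0, 0))
  # lambda = 0: no flux
  p0 <- model_params(gamma = 0, a = 0, epsilon = 0, delta = 0, lambda = 0,
                     kappa = 1)
  expect_equal(transport_terms(st, g, p0)$p, c(0, 0))
})

test_that("rhs conserves volume up to production and the two loss channels", {
  g <- shell_grid(18, 30)
  st <- spheroid_state(g, p = c(rep(1, 20), 0.6, 0.3, rep(0, 8)),
                       n = c(rep(0, 20), 0.2, 0.2, rep(0, 8)))
  p <- model_params(gamma = 0.03, a = 27.7, epsilon = 0.23, delta = 0.011,
                    lambda = 1, kappa = 18 / 16, gate_width = 0)
  r <- rs_rhs(st, g, p)
  tm <- rs_terms(st, g, r$rho, p, Pmc = 0)
  lhs <- sum(g$volumes * rowSums(r$dconc))
  rhs <- sum(tm$prolif_gain_p) + sum(tm$prolif_gain_d) -
    sum(tm$mc_loss_d) - sum(tm$decay_n)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # empty state: zero derivative
  r0 <- rs_rhs(spheroid_state(g), g, p)
  expect_true(all(r0$dconc == 0))
  # dilute, oxygenated: volume growth rate within 2% of gamma * V_total
  std <- spheroid_state(shell_grid(18, 4), p = c(0.01, rep(0, 3)))
  pd <- model_params(gamma = 0.03, a = 0, epsilon = 0, delta = 0, lambda = 0,
                     kappa = 18 / 16, gate_width = 0)
  rd <- rs_rhs(std, shell_grid(18, 4), pd)
  Vtot <- sum(shell_grid(18, 4)$volumes * rowSums(std$conc))
  expect_equal(sum(shell_grid(18, 4)$volumes * rowSums(rd$dconc)),
               0.03 * Vtot, tolerance = 0.02)
})

test_that("the integrator respects bounds, monotonicity and frozen dynamics", {
  g <- shell_grid(32, 8)
  st <- spheroid_state(g, p = c(1, 1, 0.5, rep(0, 5)))
  pz <- model_params(gamma = 0, a = 0, epsilon = 0, delta = 0, lambda = 0,
                     kappa = 2)
  trz <- simulate_spheroid(st, g, pz, t_end = 100, sample_every = 25)
  expect_identical(trz$state$conc[1:8, ], st$conc)  # bit-exact freeze
  # growing spheroid: concentrations within bounds at all samples
  p <- fadu_params()
  g2 <- shell_grid(p$dr, 8)
  tr <- simulate_spheroid(uniform_ball(100, g2), g2, p, t_end = 500,
                          sample_every = 24,
                          control = rs_control(record_profiles = TRUE))
  for (cm in tr$profiles$conc) {
    expect_true(all(cm >= 0 & cm <= 1))
    expect_true(all(rowSums(cm) <= 1 + 1e-9))
  }
  # delta = 0, no irradiation: total volume non-decreasing
  p0 <- model_params(gamma = p$gamma, a = p$physics$a, epsilon = p$epsilon,
                     delta = 0, lambda = p$lambda, kappa = p$kappa)
  tr0 <- simulate_spheroid(uniform_ball(100, g2), g2, p0, t_end = 500,
                           sample_every = 24)
  expect_true(all(diff(tr0$summary$V_total_um3) >= -1e-6))
})

test_that("an emergent necrotic core matches the closed-form inference", {
  p <- model_params(gamma = 0.03, a = 27.7, epsilon = 0.23, delta = 0.0111,
                    lambda = 2, kappa = 2)
  g <- shell_grid(p$dr, 8)
  tr <- simulate_spheroid(uniform_ball(100, g), g, p, t_end = 900,
                          sample_every = 48)
  s <- tr$summary
  est <- s[s$R_spheroid_um > 250, ]
  pred <- necrotic_from_outer(est$R_spheroid_um, p$physics)
  expect_true(all(abs(est$R_necrotic_um - pred) < p$dr))
})
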