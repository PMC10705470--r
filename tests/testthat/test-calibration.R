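test_that("fit specifications validate bounds and scales", {
  expect_error(fit_spec(list(gamma = c(0.02, 0.02))), "lower >= upper")
  expect_error(fit_spec(list(foo = c(0, 1))), "unknown free parameter")
  expect_error(fit_spec(list(gamma = c(0.01, 0.03, 0.05))), "outside")
  expect_error(fit_spec(list(epsilon = c(0, 1)), log_scale = "epsilon"),
               "positive")
  expect_error(fit_spec(list(gamma = c(0.01, 0.03)),
                        fixed = list(gamma = 0.02)), "both free and fixed")
  sp <- fit_spec(list(gamma = c(0.01, 0.03), epsilon = c(1e-4, 10)))
  expect_identical(sp$log_scale, "epsilon")
})

test_that("parameter_table encodes the literature calibration ranges", {
  sp <- parameter_table("FaDu")
  expect_equal(sp$free$gamma, log(2) / c(40, 20))
  expect_equal(sp$free$epsilon, c(1e-4, 10))
  expect_equal(sp$free$kappa, c(1, 10))
  expect_equal(sp$free$lambda_dr, c(1, 100))
  expect_equal(sp$fixed$dr_star, 16)
  expect_equal(sp$fixed$rho0, 100)
  sp2 <- parameter_table("HCT-116")
  expect_equal(sp2$free$a, c(22.1 - 4.8, 22.1 + 4.8))
  expect_equal(sp2$free$gamma, log(2) / c(36, 17.1))
  expect_warning(sp3 <- parameter_table("NoSuchLine"), "generic")
  expect_equal(sp3$free$gamma, log(2) / c(100, 10))
})

test_that("initial states hit the target radius and are memoryless", {
  p <- fadu_params()
  for (Rt in c(60, 150, 250)) {
    b <- build_initial_state(Rt, p)
    expect_equal(spheroid_radius(b$state, b$grid), Rt, tolerance = 1e-3)
    expect_identical(b$state$time, 0)
  }
  # seed stage has no anoxic core (20% of the target volume, well oxygenated)
  b <- build_initial_state(200, p)
  expect_equal(solve_oxygen(b$state, b$grid, p$physics)$anoxic_radius, 0)
  # two targets overlay after a time shift (memoryless initialization)
  b1 <- build_initial_state(100, p)
  b2 <- build_initial_state(150, p)
  t1 <- simulate_spheroid(b1$state, b1$grid, p, t_end = 500,
                          sample_every = 6)
  t2 <- simulate_spheroid(b2$state, b2$grid, p, t_end = 350,
                          sample_every = 6)
  tshift <- approx(t1$summary$R_spheroid_um, t1$summary$time_h,
                   xout = 150)$y
  R1 <- approx(t1$summary$time_h - tshift, t1$summary$R_spheroid_um,
               xout = t2$summary$time_h)$y
  expect_lt(max(abs(R1 / t2$summary$R_spheroid_um - 1), na.rm = TRUE), 1e-3)
})

test_that("a noiseless self-consistency fit recovers gamma exactly", {
  truth <- model_params(gamma = log(2) / 30, a = 9.9, epsilon = 0.36,
                        delta = 0.031, lambda = 0.8, kappa = 4.15)
  curve <- generate_fixture(truth, R_init = 60, t_end_d = 14, noise_sd = 0,
                            seed = 1)
  spec <- fit_spec(list(gamma = c(0.01, 0.04)),
                   fixed = list(a = 9.9, epsilon = 0.36, delta = 0.031,
                                lambda = 0.8, kappa = 4.15, dr_star = 16),
                   seed = 2, n_starts = 2)
  fit <- fit_growth(curve, spec)
  expect_equal(fit$estimates$gamma, truth$gamma, tolerance = 0.005)
  expect_gt(fit$r2_volume, 0.9999)
  expect_true(fit$convergence)
  # reproducibility: identical spec and seed give a bit-identical result
  fit2 <- fit_growth(curve, spec)
  expect_identical(fit$estimates, fit2$estimates)
  expect_identical(fit$objective, fit2$objective)
  expect_identical(fit$starts, fit2$starts)
})

test_that("gamma*kappa is identifiable without small radii, gamma is not", {
  # fixed synthetic benchmark: every sampled radius exceeds 3 dr
  truth <- fadu_params()
  curve <- generate_fixture(truth, R_init = 220, t_end_d = 21,
                            noise_sd = 0.03, seed = 13)
  expect_gt(min(curve$radius_um), 3 * truth$dr)
  free <- parameter_table("FaDu")$free
  spec <- fit_spec(free, fixed = list(dr_star = 16, D_rho = 2e-9,
                                      rho0 = 100, rho_an = 0),
                   weights = c(outer = 1, necrotic = 0), seed = 7,
                   n_starts = 8)
  fit <- fit_growth(curve, spec)
  st <- fit$starts
  # starts within 10% of the best residual norm are statistically
  # equivalent fits at this noise level
  near <- st[st$objective <= 1.1 * min(st$objective), ]
  expect_gte(nrow(near), 3)
  spread <- function(x) (max(x) - min(x)) / mean(x)
  expect_lt(spread(near$gamma * near$kappa), 0.10)
  expect_gt(spread(near$gamma), 0.25)
})

test_that("radiation calibration restricts frees and audits its data use", {
  base <- hct116_params()
  expect_error(
    fit_radiation(list(list(dose = 10,
                            curve = growth_curve(0:4, 200:204))),
                  base, fit_spec(list(gamma = c(0.01, 0.1)))),
    "frees must be among")
  # two-arm workflow: only the high-dose arm is touched; Pmc bounds respect
  # the < 0.5 < ordering
  rad <- hct116_rad(events = data.frame(time_h = 0, dose_Gy = 10))
  curve10 <- generate_fixture(base, R_init = 200, t_end_d = 10,
                              noise_sd = 0.02, seed = 21, rad = rad)
  rad5 <- hct116_rad(events = data.frame(time_h = 0, dose_Gy = 5))
  curve5 <- generate_fixture(base, R_init = 200, t_end_d = 10,
                             noise_sd = 0.02, seed = 22, rad = rad5)
  spec <- fit_spec(list(Pmc1 = c(0, 0.49), Pmc2 = c(0.51, 1)),
                   fixed = list(alpha = 0.5, beta = 0.042, tau_mc = 120),
                   seed = 5, n_starts = 2, max_eval = 120)
  fit <- fit_radiation(list(list(dose = 5, curve = curve5),
                            list(dose = 10, curve = curve10)), base, spec)
  expect_equal(fit$audit$stage1$dose, 10)
  expect_equal(fit$audit$predicted_doses, 5)
  expect_lt(fit$estimates$Pmc1, 0.5)
  expect_gt(fit$estimates$Pmc2, 0.5)
})
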