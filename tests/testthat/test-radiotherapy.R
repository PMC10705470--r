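rad_hct <- hct116_rad()
rad_fadu <- radiation_params(alpha = 0.35, beta = 0.079, Pmc1 = 0.16,
                             Pmc2 = 0.81)

test_that("oxygen enhancement spans m at anoxia down to 1 when oxygenated", {
  expect_equal(effective_dose(9, 0, rad_hct), 3)  # d/m at rho = 0
  expect_equal(effective_dose(10, 1e9, rad_hct), 10, tolerance = 1e-6)
  # algebraic midpoint at rho = K
  expect_equal(effective_dose(10, rad_hct$oer_K, rad_hct),
               10 * (3 + 1) / (2 * 3))
  # d_eff never exceeds d; OER decreasing in rho
  rho <- seq(0, 120, by = 1)
  de <- effective_dose(5, rho, rad_hct)
  expect_true(all(de <= 5 + 1e-12))
  expect_true(all(diff(de) > 0))
})

test_that("LQ survival matches the canonical closed form", {
  expect_equal(lq_survival(0, rad_hct), 1)
  expect_equal(lq_survival(10, rad_hct), exp(-9.2))       # 0.5, 0.042
  expect_equal(lq_survival(2, rad_fadu), exp(-1.016))     # 0.35, 0.079
  expect_equal(lq_survival(2, rad_fadu), 0.362, tolerance = 1e-3)
  # non-increasing in dose
  expect_true(all(diff(lq_survival(seq(0, 20, 0.5), rad_hct)) < 0))
})

test_that("irradiation converts p to d, conserving per-shell totals", {
  g <- shell_grid(16, 4)
  st <- spheroid_state(g, p = c(0.9, 0.8, 0.4, 0), n = c(0.1, 0, 0.1, 0))
  rho <- c(5, 20, 80, 100)
  out <- irradiate(st, g, rho, 10, rad_hct)
  expect_equal(rowSums(out$conc), rowSums(st$conc), tolerance = 1e-15)
  expect_identical(out$conc[, "n"], st$conc[, "n"])
  # survivors per shell compose effective_dose and lq_survival exactly
  S <- lq_survival(effective_dose(10, rho, rad_hct), rad_hct)
  expect_equal(out$conc[, "p"], st$conc[, "p"] * S, tolerance = 1e-12)
  expect_equal(out$conc[, "d"], st$conc[, "d"] + st$conc[, "p"] * (1 - S),
               tolerance = 1e-12)
  # hypoxic protection: the inner (hypoxic) shell keeps more p cells
  expect_gt(out$conc[1, "p"] / st$conc[1, "p"],
            out$conc[3, "p"] / st$conc[3, "p"])
  # dose 0 is the identity, and d then 0 equals d
  expect_equal(irradiate(st, g, rho, 0, rad_hct)$conc, st$conc)
  expect_equal(irradiate(out, g, rho, 0, rad_hct)$conc, out$conc)
})

test_that("mitotic-catastrophe probability steps at the switch delay", {
  expect_equal(pmc_at(0, rad_hct), 0.27)
  expect_equal(pmc_at(119.9, rad_hct), 0.27)
  expect_equal(pmc_at(120, rad_hct), 0.67)
  expect_equal(pmc_at(1e4, rad_hct), 0.67)
  rc <- radiation_params(alpha = 0.5, beta = 0.042, Pmc1 = 0.49,
                         Pmc2 = 0.51)
  # nearly constant schedule: switch nearly unobservable
  expect_equal(pmc_at(c(0, 500), rc), c(0.49, 0.51))
})

test_that("parameter validation enforces the Pmc ordering", {
  expect_error(radiation_params(0.5, 0.042, Pmc1 = 0.6, Pmc2 = 0.7))
  expect_error(radiation_params(0.5, 0.042, Pmc1 = 0.2, Pmc2 = 0.4))
  expect_error(radiation_params(0.5, 0.042, Pmc1 = 0.2, Pmc2 = 0.7,
                                events = data.frame(time_h = 0,
                                                    dose_Gy = -1)))
})

test_that("high dose controls the spheroid and low dose relapses", {
  p <- hct116_params()
  init <- build_initial_state(200, p)
  hi <- hct116_rad(events = data.frame(time_h = 0, dose_Gy = 10))
  lo <- hct116_rad(events = data.frame(time_h = 0, dose_Gy = 2))
  t_hi <- simulate_spheroid(init$state, init$grid, p, t_end = 21 * 24,
                            rad = hi, sample_every = 24)
  t_lo <- simulate_spheroid(init$state, init$grid, p, t_end = 21 * 24,
                            rad = lo, sample_every = 24)
  V0 <- t_hi$summary$V_total_um3[1]
  expect_lt(min(t_hi$summary$V_total_um3), 0.05 * V0)  # control: shrinks
  expect_gt(max(t_lo$summary$V_total_um3), V0)         # relapse: recovers
  # with Pmc = 1 and every cell damaged, the clonogenic volume never grows
  st_d <- init$state
  st_d$conc[, "d"] <- st_d$conc[, "p"] + st_d$conc[, "d"]
  st_d$conc[, "p"] <- 0
  attr(st_d, "last_irr") <- 0
  pm1 <- radiation_params(alpha = 0.5, beta = 0.042, Pmc1 = 0.27, Pmc2 = 1,
                          tau_mc = 0)
  t1 <- simulate_spheroid(st_d, init$grid, p, t_end = 240, rad = pm1,
                          sample_every = 24)
  expect_true(all(diff(t1$summary$V_p + t1$summary$V_d) <= 1e-6))
})
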