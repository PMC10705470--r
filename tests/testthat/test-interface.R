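test_that("growth-curve CSV round-trips and rejects malformed input", {
  cv <- growth_curve(c(0, 1, 2.5), c(100.123456789, 110.5, 130.25),
                     c(0, 0, 12.75))
  f <- tempfile(fileext = ".csv")
  write_growth_curve(cv, f)
  back <- read_growth_curve(f)
  expect_equal(back$time_d, cv$time_d, tolerance = 1e-12)
  expect_equal(back$radius_um, cv$radius_um, tolerance = 1e-12)
  expect_equal(back$necrotic_radius_um, cv$necrotic_radius_um,
               tolerance = 1e-12)
  # shuffled rows: error names the first offending row
  writeLines(c("time_d,radius_um", "0,100", "2,120", "1,110"), f)
  expect_error(read_growth_curve(f), "row 3")
  writeLines(c("days,r", "0,100"), f)
  expect_error(read_growth_curve(f), "header")
  # curve without the optional necrotic column
  writeLines(c("time_d,radius_um", "0,100", "1,110", "2,120"), f)
  expect_null(read_growth_curve(f)$necrotic_radius_um)
  unlink(f)
})

test_that("fixtures are exact without noise and seeded with it", {
  p <- fadu_params()
  clean <- generate_fixture(p, R_init = 80, t_end_d = 10, noise_sd = 0,
                            seed = 1)
  init <- build_initial_state(80, p)
  tr <- simulate_spheroid(init$state, init$grid, p, t_end = 240,
                          sample_every = 24)
  expect_equal(clean$radius_um, tr$summary$R_spheroid_um, tolerance = 1e-12)
  expect_equal(nrow(clean), 11)  # daily sampling including day 0
  # identical seed, identical fixture; different seed differs
  n1 <- generate_fixture(p, R_init = 80, t_end_d = 10, noise_sd = 0.03,
                         seed = 7)
  n2 <- generate_fixture(p, R_init = 80, t_end_d = 10, noise_sd = 0.03,
                         seed = 7)
  n3 <- generate_fixture(p, R_init = 80, t_end_d = 10, noise_sd = 0.03,
                         seed = 8)
  expect_identical(n1$radius_um, n2$radius_um)
  expect_false(identical(n1$radius_um, n3$radius_um))
  # distributional check on a ~3-week curve at 3% noise
  p2 <- fadu_params()
  clean21 <- generate_fixture(p2, R_init = 60, t_end_d = 21, noise_sd = 0,
                              seed = 1)
  noisy21 <- generate_fixture(p2, R_init = 60, t_end_d = 21, noise_sd = 0.03,
                              seed = 2)
  s <- sd(log(noisy21$radius_um / clean21$radius_um))
  expect_lt(abs(s - 0.03) / 0.03, 0.2)
  # ground truth travels with the fixture
  expect_equal(attr(n1, "truth")$gamma, p$gamma)
  expect_equal(attr(n1, "truth")$gamma_kappa_dr, p$gamma * p$dr)
})

test_that("run configurations round-trip through JSON with a stable hash", {
  cfg <- list(model = list(gamma = 0.02, a = 9.9, epsilon = 0.36,
                           delta = 0.031, lambda = 0.8, kappa = 4.15),
              radiation = list(alpha = 0.35, beta = 0.079, Pmc1 = 0.16,
                               Pmc2 = 0.81,
                               events = data.frame(time_h = 0, dose_Gy = 5)),
              simulation = list(R_init_um = 100, t_end_d = 5), seed = 3)
  f <- tempfile(fileext = ".json")
  write_run_config(cfg, f)
  rc <- read_run_config(f)
  expect_s3_class(rc$params, "rs_params")
  expect_equal(rc$params$kappa, 4.15)
  expect_s3_class(rc$rad, "radiation_params")
  expect_equal(unname(rc$rad$events[1, "dose_Gy"]), 5)
  expect_match(attr(rc, "hash"), "^[0-9a-f]{32}$")
  expect_identical(attr(rc, "hash"), attr(read_run_config(f), "hash"))
  unlink(f)
})

test_that("the command-line interface wires the module operations", {
  d <- withr::local_tempdir()
  cfgp <- file.path(d, "cfg.json")
  write_run_config(list(model = list(gamma = 0.02, a = 9.9, epsilon = 0.36,
                                     delta = 0.031, lambda = 0.8,
                                     kappa = 4.15),
                        simulation = list(R_init_um = 100, t_end_d = 3),
                        seed = 1), cfgp)
  expect_output(code <- rs_cli(c("neighborhood-stats", "--kind", "moore",
                                 "--order", "3")), "dneigh = 3.34263")
  expect_equal(code, 0L)
  out1 <- file.path(d, "sim1")
  expect_output(rs_cli(c("simulate", "--config", cfgp, "--out", out1)),
                "trajectory.csv")
  tj <- utils::read.csv(file.path(out1, "trajectory.csv"))
  expect_named(tj, c("time_d", "R_spheroid_um", "R_necrotic_um",
                     "V_total_um3", "V_p", "V_d", "V_n"))
  expect_true(file.exists(file.path(out1, "run_info.json")))
  # deterministic: a second run writes an identical trajectory
  out2 <- file.path(d, "sim2")
  expect_output(rs_cli(c("simulate", "--config", cfgp, "--out", out2)))
  expect_identical(readLines(file.path(out1, "trajectory.csv")),
                   readLines(file.path(out2, "trajectory.csv")))
  # fixture + necrotic inference chain
  outf <- file.path(d, "fx")
  expect_output(rs_cli(c("fixture", "--config", cfgp, "--r-init", "80",
                         "--noise", "0.02", "--seed", "4", "--out", outf)),
                "fixture.csv")
  expect_true(file.exists(file.path(outf, "fixture.truth.json")))
  outn <- file.path(d, "nec")
  expect_output(rs_cli(c("infer-necrotic", "--curve",
                         file.path(outf, "fixture.csv"), "--a", "27.7",
                         "--out", outn)), "curve_with_necrotic.csv")
  nec <- read_growth_curve(file.path(outn, "curve_with_necrotic.csv"))
  expect_false(is.null(nec$necrotic_radius_um))
  # failure modes exit non-zero with a message
  expect_message(code <- rs_cli("frobnicate"), "unknown subcommand")
  expect_equal(code, 1L)
  expect_message(code <- rs_cli(c("simulate", "--config")), "value")
  expect_equal(code, 1L)
})
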