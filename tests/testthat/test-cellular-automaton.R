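test_that("neighborhood offset sets have the expected cardinality", {
  expect_equal(nrow(neighborhood_offsets("moore", 1)), 26)
  expect_equal(nrow(neighborhood_offsets("moore", 3)), 342)
  expect_equal(nrow(neighborhood_offsets("moore", 4)), 728)
  expect_equal(nrow(neighborhood_offsets("von_neumann", 1)), 6)
  expect_error(neighborhood_offsets("moore", 0), "k must be")
})

test_that("mean neighbor distances match enumeration and printed values", {
  expect_equal(mean_neighbor_distance(neighborhood_spec("von_neumann", 1)), 1)
  expect_equal(mean_neighbor_distance(neighborhood_spec("moore", 1)),
               (6 + 12 * sqrt(2) + 8 * sqrt(3)) / 26, tolerance = 1e-12)
  expect_equal(round(mean_neighbor_distance(neighborhood_spec("moore", 3)), 2),
               3.34)
  expect_equal(round(mean_neighbor_distance(neighborhood_spec("moore", 4)), 2),
               4.31)
  # continuous-cube sanity oracle 0.9606 (k + 1/2)
  for (k in 1:5)
    expect_lt(abs(mean_neighbor_distance(neighborhood_spec("moore", k)) -
                    0.9606 * (k + 0.5)), 0.03)
})

test_that("the kappa transfer relation and its inversion round-trip", {
  expect_equal(kappa_from_neighborhood(neighborhood_spec("moore", 3)),
               1.19 * mean_neighbor_distance(neighborhood_spec("moore", 3)) -
                 0.29)
  ns <- neighborhood_spec(c("moore", "moore"), c(3, 4))
  expect_equal(round(kappa_from_neighborhood(ns), 2), 4.26)
  # exact hit returns the pure neighborhood
  k2 <- kappa_from_neighborhood(neighborhood_spec("moore", 2))
  sp2 <- neighborhood_for_kappa(k2)
  expect_equal(nrow(sp2$components), 1)
  expect_equal(sp2$components$order, 2L)
  # round-trip identity across the covered range
  for (x in seq(1.2, 8, by = 0.35))
    expect_equal(kappa_from_neighborhood(neighborhood_for_kappa(x)), x,
                 tolerance = 1e-12)
  expect_warning(neighborhood_for_kappa(50), "outside")
  expect_warning(kappa_from_neighborhood(neighborhood_spec("von_neumann", 1)),
                 "validity")
})

test_that("single sweeps honor division, space limits and the shuffle", {
  ns <- neighborhood_spec("moore", 1)
  pfast <- model_params(gamma = 10, a = 0, epsilon = 0, delta = 0,
                        lambda = 0, kappa = 1.4)
  # forced division of a single cell doubles the population
  w1 <- ca_world(8)
  expect_equal(sum(ca_counts(w1)), 1)
  w2 <- ca_step(w1, pfast, ns, dt = 0.1, seed = 3, check_dt = FALSE)
  expect_equal(sum(ca_counts(w2)), 2)
  expect_equal(attr(w2, "n_divisions"), 1)
  # packed interior: only cells near the surface can divide
  wb <- ca_world(80)
  n0 <- sum(ca_counts(wb))
  wb2 <- ca_step(wb, pfast, ns, dt = 0.1, seed = 4, check_dt = FALSE)
  added <- sum(ca_counts(wb2)) - n0
  expect_gt(added, 0)
  expect_lt(added, 0.8 * n0)  # interior cells are blocked by full neighborhoods
  # voxel bookkeeping is exact
  expect_equal(added, attr(wb2, "n_divisions") - attr(wb2, "n_removals"))
  # dt invariant is enforced
  expect_error(ca_step(wb, pfast, ns, dt = 0.1, seed = 1),
               "Monte Carlo step too long")
  # after the shuffle no cell has an empty strictly-closer face neighbor
  arr <- array(wb2$state, rep(wb2$L, 3))
  c0 <- (wb2$L + 1) / 2
  occ <- which(arr != 0, arr.ind = TRUE)
  faces <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  viol <- 0L
  for (i in seq_len(nrow(occ))) {
    x <- occ[i, ]
    r2 <- sum((x - c0)^2)
    for (f in seq_len(6)) {
      y <- x + faces[f, ]
      if (arr[y[1], y[2], y[3]] == 0 && sum((y - c0)^2) < r2 - 1e-9)
        viol <- viol + 1L
    }
  }
  expect_equal(viol, 0L)
})

test_that("ensembles are frozen without rates, reproducible, and tighten", {
  ns <- neighborhood_spec("moore", 1)
  p0 <- model_params(gamma = 0, a = 0, epsilon = 0, delta = 0, lambda = 0,
                     kappa = 1.4)
  e0 <- ca_simulate(p0, ns, R_init = 50, t_end = 10, n_runs = 2, seed = 1,
                    dt = 1, sample_every = 5)
  for (r in e0$runs)
    expect_true(all(r$R_spheroid_um == r$R_spheroid_um[1]))
  # identical seeds reproduce bit-exactly
  p <- model_params(gamma = 0.05, a = 0, epsilon = 0, delta = 0, lambda = 0,
                    kappa = 1.4)
  e1 <- ca_simulate(p, ns, R_init = 40, t_end = 48, n_runs = 2, seed = 9,
                    sample_every = 24)
  e2 <- ca_simulate(p, ns, R_init = 40, t_end = 48, n_runs = 2, seed = 9,
                    sample_every = 24)
  expect_identical(e1$runs, e2$runs)
  # run-to-run spread of the final radius shrinks with spheroid size
  rel_sd <- function(R_init) {
    e <- ca_simulate(p, ns, R_init = R_init, t_end = 72, n_runs = 4,
                     seed = 11, sample_every = 72)
    Rf <- vapply(e$runs, function(r) r$R_spheroid_um[nrow(r)], numeric(1))
    sd(Rf) / mean(Rf)
  }
  expect_lt(rel_sd(70), rel_sd(25))
})

test_that("anoxic cores and removals emerge in large lattice spheroids", {
  # strong consumption so a 100 um ball develops a core quickly
  p <- model_params(gamma = 0.02, a = 200, epsilon = 0.4, delta = 0.1,
                    lambda = 0, kappa = 1.4)
  e <- ca_simulate(p, neighborhood_spec("moore", 1), R_init = 100,
                   t_end = 48, n_runs = 1, seed = 2, sample_every = 24)
  r <- e$runs[[1]]
  expect_gt(r$R_necrotic_um[nrow(r)], 0)
  expect_lt(r$R_necrotic_um[nrow(r)], r$R_spheroid_um[nrow(r)])
  expect_gt(e$bookkeeping[[1]][["n_removals"]], 0)
})
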