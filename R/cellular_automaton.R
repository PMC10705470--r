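#' Lattice neighborhood specification
#'
#' A (possibly mixed) interaction neighborhood for the 3D cellular automaton:
#' one or more Moore (Chebyshev-ball) or von Neumann (Manhattan-ball)
#' components of integer order with alternation weights summing to 1. The
#' component drawn (per division attempt, by weight) bounds where a daughter
#' cell may be placed.
#'
#' @param kind character vector, each `"moore"` or `"von_neumann"`.
#' @param order integer orders `k >= 1`.
#' @param weight alternation weights; must sum to 1 (default: equal).
#' @return An object of class `neighborhood_spec`.
#' @examples
#' neighborhood_spec("moore", 3)
#' neighborhood_spec(c("moore", "moore"), c(3, 4))  # 50:50 alternation
#' @export
neighborhood_spec <- function(kind, order, weight = NULL) {
  kind <- match.arg(kind, c("moore", "von_neumann"), several.ok = TRUE)
  kind <- rep_len(kind, length(order))
  if (is.null(weight)) weight <- rep(1 / length(order), length(order))
  stopifnot(length(weight) == length(order), all(order >= 1),
            all(order == round(order)), all(weight >= 0))
  if (abs(sum(weight) - 1) > 1e-9) stop("weights must sum to 1")
  spec <- list(components = data.frame(kind = kind,
                                       order = as.integer(order),
                                       weight = weight))
  class(spec) <- "neighborhood_spec"
  spec
}

#' @export
print.neighborhood_spec <- function(x, ...) {
  cat("<neighborhood_spec>\n")
  with(x$components,
       cat(sprintf("  %s k=%d (weight %.3g, dneigh %.4g)\n", kind, order,
                   weight,
                   mapply(function(k, o)
                     mean(sqrt(rowSums(neighborhood_offsets(k, o)^2))),
                     kind, order)), sep = ""))
  cat(sprintf("  dneigh = %.4g, kappa = %.4g\n", mean_neighbor_distance(x),
              kappa_from_neighborhood(x)))
  invisible(x)
}

#' Integer offsets of a lattice neighborhood
#'
#' Moore order `k`: all sites with Chebyshev distance `max(|x|,|y|,|z|) <= k`
#' except the origin (`(2k+1)^3 - 1` sites). Von Neumann order `k`: Manhattan
#' distance `|x|+|y|+|z| <= k` except the origin.
#'
#' @param kind `"moore"` or `"von_neumann"`.
#' @param k order (integer >= 1).
#' @return Integer matrix with columns x, y, z.
#' @export
neighborhood_offsets <- function(kind, k) {
  kind <- match.arg(kind, c("moore", "von_neumann"))
  if (k < 1 || k != round(k)) stop("order k must be an integer >= 1")
  g <- as.matrix(expand.grid(x = -k:k, y = -k:k, z = -k:k))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (kind == "von_neumann") g <- g[rowSums(abs(g)) <= k, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

#' Mean neighbor distance of a neighborhood
#'
#' Weighted average (over components) of the mean Euclidean offset length, in
#' units of the cell diameter. This is the quantity the shell-width multiplier
#' `kappa` maps to.
#'
#' @param spec a [neighborhood_spec()].
#' @return Dimensionless mean neighbor distance.
#' @examples
#' mean_neighbor_distance(neighborhood_spec("moore", 3))  # ~3.34
#' @export
mean_neighbor_distance <- function(spec) {
  stopifnot(inherits(spec, "neighborhood_spec"))
  comp <- spec$components
  d <- mapply(function(k, o)
    mean(sqrt(rowSums(neighborhood_offsets(k, o)^2))), comp$kind, comp$order)
  sum(comp$weight * d)
}

#' Shell-width multiplier implied by a neighborhood
#'
#' The empirical linear transfer relation `kappa = 1.19 * dneigh - 0.29`
#' between the mean neighbor distance of a cellular-automaton neighborhood and
#' the radial-shell width multiplier.
#'
#' @param spec a [neighborhood_spec()].
#' @return Dimensionless `kappa` (values below 1 are outside the relation's
#'   validity and trigger a warning).
#' @export
kappa_from_neighborhood <- function(spec) {
  k <- 1.19 * mean_neighbor_distance(spec) - 0.29
  if (k < 1)
    warning("kappa = ", format(k), " < 1: outside the validity of the transfer relation")
  k
}

# single-kind candidates ordered by mean distance (internal)
kappa_candidates <- function(max_order = 8L) {
  cands <- rbind(
    data.frame(kind = "von_neumann", order = 1L),
    data.frame(kind = "moore", order = seq_len(max_order)))
  cands$dneigh <- mapply(function(k, o)
    mean(sqrt(rowSums(neighborhood_offsets(k, o)^2))), cands$kind, cands$order)
  cands[order(cands$dneigh), ]
}

#' Neighborhood realizing a target kappa
#'
#' Inverts the linear transfer relation: picks the two adjacent single-kind
#' neighborhoods whose implied `kappa` bracket the target and returns the
#' two-component alternation whose weighted mean distance inverts the map
#' exactly (a pure neighborhood if the target is hit exactly). Falls back to
#' the nearest single neighborhood, with a warning, outside the covered range.
#'
#' @param kappa_target target shell-width multiplier (>= 1).
#' @param max_order largest Moore order considered.
#' @return A [neighborhood_spec()].
#' @examples
#' neighborhood_for_kappa(4.26)  # ~50:50 moore k=3 / k=4
#' @export
neighborhood_for_kappa <- function(kappa_target, max_order = 8L) {
  stopifnot(kappa_target >= 1)
  cands <- kappa_candidates(max_order)
  d_target <- (kappa_target + 0.29) / 1.19
  hit <- which(abs(cands$dneigh - d_target) < 1e-9)
  if (length(hit))
    return(neighborhood_spec(cands$kind[hit[1]], cands$order[hit[1]], 1))
  if (d_target < min(cands$dneigh) || d_target > max(cands$dneigh)) {
    i <- which.min(abs(cands$dneigh - d_target))
    warning("target kappa outside covered range; using nearest single neighborhood")
    return(neighborhood_spec(cands$kind[i], cands$order[i], 1))
  }
  j <- which(cands$dneigh > d_target)[1]
  i <- j - 1L
  w <- (d_target - cands$dneigh[i]) / (cands$dneigh[j] - cands$dneigh[i])
  neighborhood_spec(c(cands$kind[i], cands$kind[j]),
                    c(cands$order[i], cands$order[j]), c(1 - w, w))
}

# ---------------------------------------------------------------------------

#' Cellular-automaton world
#'
#' A cubic lattice with one cell per voxel and spacing equal to the
#' single-cell diameter, initialized as a dense ball of proliferation-
#' competent cells (compacted by one inwards shuffle).
#'
#' @param R_init initial ball radius, um.
#' @param dr_star lattice spacing / cell diameter, um (default 16).
#' @param margin extra empty voxels kept around the population.
#' @return An object of class `ca_world`: list with `state` (integer vector,
#'   0 empty / 1 p / 2 d / 3 n), `L` (lattice edge), `dr_star` and `time`.
#' @export
ca_world <- function(R_init, dr_star = 16, margin = 8L) {
  stopifnot(R_init > 0, dr_star > 0)
  res <- cpp_ca_simulate(dr_star, cpp_pars(null_ca_params(dr_star)),
                         null_radiation(), matrix(numeric(0), 0, 2),
                         list(neighborhood_offsets("moore", as.integer(margin))),
                         1, R_init, 0, 1, numeric(0), 1, dr_star, 4L,
                         NULL, 0L, TRUE, FALSE)
  w <- list(state = res$state, L = res$L, dr_star = dr_star, time = 0)
  class(w) <- "ca_world"
  w
}

# inert parameter set used when only geometry is needed (internal)
null_ca_params <- function(dr_star) {
  model_params(gamma = 0, a = 0, epsilon = 0, delta = 0, lambda = 0,
               kappa = 1, dr_star = dr_star)
}

#' @export
print.ca_world <- function(x, ...) {
  n <- ca_counts(x)
  cat(sprintf("<ca_world> L=%d, t=%.4g h: %d p, %d d, %d n cells\n",
              x$L, x$time, n[["p"]], n[["d"]], n[["n"]]))
  invisible(x)
}

#' Voxel counts per cell type
#' @param world a [ca_world()].
#' @return Named integer vector with counts of `p`, `d` and `n` voxels.
#' @export
ca_counts <- function(world) {
  c(p = sum(world$state == 1L), d = sum(world$state == 2L),
    n = sum(world$state == 3L))
}

# Monte Carlo step length satisfying dt * max(rate) <= 0.1 (internal)
ca_default_dt <- function(params) {
  mx <- max(params$gamma, params$epsilon, params$delta)
  if (mx <= 0) return(1)
  0.1 / mx
}

#' One Monte Carlo sweep of the cellular automaton
#'
#' Performs a single step of length `dt`: oxygen is solved on the radialized
#' occupancy (shells of one cell diameter), every proliferation-competent or
#' damaged cell attempts division with probability `gamma * dt` where
#' `rho > rho_h` (damaged cells are removed with probability `Pmc` at the
#' attempt, otherwise the daughter goes to a uniformly drawn free site of the
#' drawn neighborhood component), anoxic cells convert to membrane-defect with
#' probability `epsilon * dt`, membrane-defect cells are removed with
#' probability `delta * dt`, and a rate-independent inwards shuffle restores
#' compactness.
#'
#' @param world a [ca_world()].
#' @param params an [model_params()] (only `gamma`, `a`, `epsilon`, `delta`,
#'   `rho_h` and the physics transfer; `lambda` and `dr` have no counterpart).
#' @param neighborhood a [neighborhood_spec()].
#' @param dt Monte Carlo step, hours; must satisfy
#'   `dt * max(gamma, epsilon, delta) <= 0.1`.
#' @param Pmc mitotic-catastrophe probability for this step.
#' @param seed integer RNG seed for the sweep.
#' @param check_dt set `FALSE` to bypass the step-length invariant (useful
#'   only for limiting-case experiments such as forced division).
#' @param placement daughter placement rule: `"uniform_free"` (default: the
#'   daughter is placed uniformly on the free sites of the drawn component,
#'   so division succeeds whenever any site is free) or `"draw_and_fail"`
#'   (one site is drawn uniformly and the division fails if it is occupied,
#'   damping division by the free fraction of the neighborhood). The two
#'   rules bracket the radial-shell growth speed: at equal transferred
#'   parameters, `uniform_free` fronts advance about twice as fast as the
#'   shell model and `draw_and_fail` about half as fast (see the vignette).
#' @return The updated [ca_world()], with bookkeeping attributes
#'   `n_divisions` and `n_removals`.
#' @export
ca_step <- function(world, params, neighborhood, dt = ca_default_dt(params),
                    Pmc = 0, seed = 1,
                    placement = c("uniform_free", "draw_and_fail"),
                    check_dt = TRUE) {
  placement <- match.arg(placement)
  stopifnot(inherits(world, "ca_world"), inherits(params, "rs_params"),
            inherits(neighborhood, "neighborhood_spec"))
  if (check_dt &&
      dt * max(params$gamma, params$epsilon, params$delta) > 0.1 + 1e-12)
    stop("Monte Carlo step too long: dt * max(gamma, epsilon, delta) must be <= 0.1")
  offs <- lapply(seq_len(nrow(neighborhood$components)), function(i)
    neighborhood_offsets(neighborhood$components$kind[i],
                         neighborhood$components$order[i]))
  rad <- null_radiation()
  rad$Pmc1 <- Pmc
  rad$Pmc2 <- Pmc
  res <- cpp_ca_simulate(world$dr_star, cpp_pars(params), rad,
                         matrix(numeric(0), 0, 2), offs,
                         neighborhood$components$weight, 0, dt, dt,
                         numeric(0), seed, world$dr_star, 4L,
                         world$state, world$L, FALSE,
                         placement == "uniform_free")
  out <- list(state = res$state, L = res$L, dr_star = world$dr_star,
              time = world$time + dt)
  class(out) <- "ca_world"
  attr(out, "n_divisions") <- res$n_divisions
  attr(out, "n_removals") <- res$n_removals
  out
}

#' Ensemble cellular-automaton simulation with transferred parameters
#'
#' Runs independent seeded realizations of the 3D lattice model from a dense
#' ball of proliferation-competent cells, recording volume-equivalent outer
#' and necrotic radii and radial concentration profiles. All radial-shell
#' parameters transfer directly except the inward transport rate `lambda`
#' (replaced by the shuffle) and the shell width `dr` (realized by the
#' neighborhood).
#'
#' @param params an [model_params()] object.
#' @param neighborhood a [neighborhood_spec()]; defaults to
#'   [neighborhood_for_kappa()] of `params$kappa`.
#' @param R_init initial ball radius, um.
#' @param t_end horizon, hours.
#' @param n_runs number of independent realizations.
#' @param seed base seed; run `i` uses `seed + i - 1`.
#' @param rad optional [radiation_params()] with events.
#' @param dt Monte Carlo step, hours (default `0.1 / max(rates)`).
#' @param sample_every sampling cadence, hours.
#' @param profile_dr shell width for recorded radial profiles, um
#'   (default `params$dr`, matching the radial-shell grid).
#' @param profile_nmax number of profile shells.
#' @param placement daughter placement rule, see [ca_step()].
#' @return An object of class `ca_ensemble`: list with `runs` (per-run data
#'   frames `time_h`, `R_spheroid_um`, `R_necrotic_um`), `profiles` (per run,
#'   per sample `n x 3` concentration matrices on the `profile_dr` grid),
#'   `bookkeeping`, and the settings used.
#' @export
ca_simulate <- function(params, neighborhood = NULL, R_init, t_end,
                        n_runs = 10, seed = 1, rad = NULL,
                        dt = ca_default_dt(params), sample_every = 24,
                        profile_dr = params$dr,
                        profile_nmax = ceiling(6 * R_init / profile_dr) + 8,
                        placement = c("uniform_free", "draw_and_fail")) {
  placement <- match.arg(placement)
  stopifnot(inherits(params, "rs_params"), n_runs >= 1)
  if (is.null(neighborhood)) neighborhood <- neighborhood_for_kappa(params$kappa)
  if (dt * max(params$gamma, params$epsilon, params$delta) > 0.1 + 1e-12)
    stop("Monte Carlo step too long: dt * max(gamma, epsilon, delta) must be <= 0.1")
  offs <- lapply(seq_len(nrow(neighborhood$components)), function(i)
    neighborhood_offsets(neighborhood$components$kind[i],
                         neighborhood$components$order[i]))
  rl <- if (is.null(rad)) null_radiation() else unclass(rad)
  ev <- rl$events
  if (is.data.frame(ev)) ev <- as.matrix(ev)
  if (is.null(ev) || length(ev) == 0) ev <- matrix(numeric(0), 0, 2)
  sample_times <- seq(0, t_end, by = sample_every)
  runs <- vector("list", n_runs)
  profs <- vector("list", n_runs)
  book <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    res <- cpp_ca_simulate(params$dr_star, cpp_pars(params), rl, ev, offs,
                           neighborhood$components$weight, R_init, t_end, dt,
                           sample_times, seed + i - 1, profile_dr,
                           as.integer(profile_nmax), NULL, 0L, TRUE,
                           placement == "uniform_free")
    runs[[i]] <- data.frame(time_h = res$time, R_spheroid_um = res$R,
                            R_necrotic_um = res$Rn)
    profs[[i]] <- res$profiles
    book[[i]] <- c(n_initial = res$n_initial, n_final = res$n_final,
                   n_divisions = res$n_divisions, n_removals = res$n_removals)
  }
  out <- list(runs = runs, profiles = profs, bookkeeping = book,
              params = params, neighborhood = neighborhood, dt = dt,
              sample_times = sample_times, profile_dr = profile_dr,
              seed = seed, R_init = R_init)
  class(out) <- "ca_ensemble"
  out
}

#' @export
print.ca_ensemble <- function(x, ...) {
  Rfin <- vapply(x$runs, function(r) r$R_spheroid_um[nrow(r)], numeric(1))
  cat(sprintf(
    "<ca_ensemble> %d runs, dt=%.3g h; final R = %.4g +/- %.3g um\n",
    length(x$runs), x$dt, mean(Rfin), stats::sd(Rfin)))
  invisible(x)
}

#' Ensemble mean growth curve of a cellular-automaton ensemble
#' @param ens a `ca_ensemble`.
#' @return Data frame `time_h`, `R_spheroid_um`, `R_necrotic_um` of
#'   ensemble means at each sample time.
#' @export
ca_ensemble_mean <- function(ens) {
  stopifnot(inherits(ens, "ca_ensemble"))
  data.frame(
    time_h = ens$runs[[1]]$time_h,
    R_spheroid_um = rowMeans(sapply(ens$runs, `[[`, "R_spheroid_um")),
    R_necrotic_um = rowMeans(sapply(ens$runs, `[[`, "R_necrotic_um")))
}
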