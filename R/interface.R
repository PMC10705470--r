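#' Read a growth curve from CSV
#'
#' Expects the dialect `time_d,radius_um[,necrotic_radius_um]` (decimal
#' point, UTF-8). Validation is strict: the header must match, times must be
#' strictly increasing and radii non-negative; errors name the offending row.
#'
#' @param path CSV file path.
#' @return A [growth_curve()].
#' @export
read_growth_curve <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_d", "radius_um")
  if (!all(need %in% names(df)) ||
      !all(names(df) %in% c(need, "necrotic_radius_um")))
    stop("malformed header in ", path,
         ": expected time_d,radius_um[,necrotic_radius_um]")
  bad <- which(diff(df$time_d) <= 0)
  if (length(bad))
    stop("times not strictly increasing at row ", bad[1] + 1, " of ", path)
  bad <- which(df$radius_um < 0 |
                 (if (is.null(df$necrotic_radius_um)) FALSE
                  else df$necrotic_radius_um < 0))
  if (length(bad)) stop("negative radius at row ", bad[1], " of ", path)
  growth_curve(df$time_d, df$radius_um, df$necrotic_radius_um)
}

#' Write a growth curve to CSV
#'
#' @param curve a [growth_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_curve <- function(curve, path) {
  stopifnot(inherits(curve, "growth_curve"))
  utils::write.csv(as.data.frame(unclass(curve)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export a trajectory summary to CSV
#'
#' Dialect: `time_d,R_spheroid_um,R_necrotic_um,V_total_um3,V_p,V_d,V_n`
#' (time converted to days at the file boundary).
#'
#' @param traj an `rs_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rs_trajectory"))
  s <- traj$summary
  out <- data.frame(time_d = s$time_h / 24, s[, -1, drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic growth-curve fixture
#'
#' Simulates the radial-shell model from an initial state built for `R_init`,
#' samples daily (emulating ~3 weeks of spheroid monitoring), and multiplies
#' the radii by lognormal measurement noise `exp(N(0, noise_sd^2))`. The
#' ground-truth parameters travel with the curve (attribute `truth`, and a
#' sidecar JSON when `path` is given) for parameter-recovery tests.
#'
#' @param params an [model_params()] object (the ground truth).
#' @param R_init initial radius at day 0, um.
#' @param t_end_d monitoring horizon in days (default 21; daily sampling).
#' @param noise_sd standard deviation of the lognormal radius noise
#'   (e.g. 0.03 for ~3% multiplicative noise).
#' @param seed RNG seed.
#' @param rad optional [radiation_params()] whose events (hours, relative to
#'   day 0) are applied during the simulation.
#' @param path optional basename: writes `<path>.csv` and `<path>.truth.json`.
#' @param control see [rs_control()].
#' @return A [growth_curve()] with necrotic radii and attribute `truth`.
#' @export
generate_fixture <- function(params, R_init, t_end_d = 21, noise_sd = 0,
                             seed = 1, rad = NULL, path = NULL,
                             control = rs_control()) {
  stopifnot(inherits(params, "rs_params"), noise_sd >= 0)
  init <- build_initial_state(R_init, params, control = control)
  traj <- simulate_spheroid(init$state, init$grid, params,
                            t_end = t_end_d * 24, rad = rad,
                            sample_every = 24, control = control)
  s <- traj$summary
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  fac_o <- exp(stats::rnorm(nrow(s), 0, noise_sd))
  fac_n <- exp(stats::rnorm(nrow(s), 0, noise_sd))
  curve <- growth_curve(s$time_h / 24, s$R_spheroid_um * fac_o,
                        s$R_necrotic_um * fac_n)
  truth <- list(gamma = params$gamma, a = params$physics$a,
                epsilon = params$epsilon, delta = params$delta,
                lambda = params$lambda, kappa = params$kappa,
                dr_star = params$dr_star,
                lambda_dr = params$lambda * params$dr,
                gamma_kappa_dr = params$gamma * params$dr,
                noise_sd = noise_sd, seed = seed, R_init = R_init)
  if (!is.null(rad))
    truth <- c(truth, list(alpha = rad$alpha, beta = rad$beta,
                           Pmc1 = rad$Pmc1, Pmc2 = rad$Pmc2,
                           tau_mc = rad$tau_mc))
  attr(curve, "truth") <- truth
  if (!is.null(path)) {
    write_growth_curve(curve, paste0(path, ".csv"))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  curve
}

# ---------------------------------------------------------------------------
# run configuration (JSON)

#' Read / write a run configuration
#'
#' A run configuration bundles model and radiation parameters, grid and
#' sampling settings, the event list and seeds as one JSON document. Reading
#' re-validates through the parameter constructors; every configuration
#' carries a content hash so outputs can be traced to it.
#'
#' @param path JSON file path.
#' @return `read_run_config`: a list with elements `params`
#'   ([model_params()]), `rad` ([radiation_params()] or `NULL`) and the
#'   remaining settings, plus attribute `hash`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(model_params, cfg$model)
  rad <- NULL
  if (!is.null(cfg$radiation)) {
    rd <- cfg$radiation
    if (!is.null(rd$events)) rd$events <- as.data.frame(rd$events)
    rad <- do.call(radiation_params, rd)
  }
  out <- list(params = params, rad = rad,
              simulation = cfg$simulation, seed = cfg$seed)
  attr(out, "hash") <- config_hash(cfg)
  out
}

#' @rdname read_run_config
#' @param config a list as produced by deparsing a configuration (fields
#'   `model`, optional `radiation`, `simulation`, `seed`).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
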