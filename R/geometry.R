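#' Radial shell grid
#'
#' Discretizes the spheroid into concentric shells of constant width `dr`.
#' Shell `i` (0-based) spans radii `[i*dr, (i+1)*dr]`, is centered at
#' `r_i = dr*(i + 1/2)` and has volume
#' `V_i = 4/3*pi*dr^3*((i+1)^3 - i^3)`, which increases outwards and sums
#' telescopically to the volume of a sphere of radius `n_shells*dr`.
#'
#' @param dr shell width in micrometers (> 0).
#' @param n_shells number of shells (>= 2).
#' @return An object of class `shell_grid`: a list with elements `dr`,
#'   `n_shells`, `centers` (shell center radii, um) and `volumes` (um^3).
#' @examples
#' g <- shell_grid(16, 4)
#' g$centers            # 8 24 40 56
#' sum(g$volumes)       # equals 4/3*pi*(4*16)^3
#' @export
shell_grid <- function(dr, n_shells) {
  if (!is.numeric(dr) || length(dr) != 1L || !is.finite(dr) || dr <= 0)
    stop("`dr` must be a single positive number (micrometers)")
  if (!is.numeric(n_shells) || length(n_shells) != 1L || n_shells < 2 ||
      n_shells != round(n_shells))
    stop("`n_shells` must be an integer >= 2")
  n_shells <- as.integer(n_shells)
  i <- seq_len(n_shells) - 1
  g <- list(dr = dr, n_shells = n_shells, centers = dr * (i + 0.5),
            volumes = 4 / 3 * pi * dr^3 * ((i + 1)^3 - i^3))
  class(g) <- "shell_grid"
  g
}

#' @export
print.shell_grid <- function(x, ...) {
  cat(sprintf("<shell_grid> %d shells of width %.4g um (outer boundary %.4g um)\n",
              x$n_shells, x$dr, x$n_shells * x$dr))
  invisible(x)
}

#' Spheroid state on a shell grid
#'
#' Per-shell concentrations of the three cell types, as fractions of maximal
#' dense packing: `p` (proliferation-competent), `d` (radiation-damaged, only
#' populated after irradiation) and `n` (membrane-defect, secondary necrotic).
#' Each concentration lies in `[0, 1]` and their per-shell sum cannot exceed 1.
#'
#' @param grid a [shell_grid()].
#' @param p,d,n per-shell concentrations; scalars are recycled. Defaults 0.
#' @param time state time in hours.
#' @return An object of class `spheroid_state`: a list with `time` (hours) and
#'   `conc`, an `n_shells x 3` matrix with columns `p`, `d`, `n`.
#' @export
spheroid_state <- function(grid, p = 0, d = 0, n = 0, time = 0) {
  stopifnot(inherits(grid, "shell_grid"))
  ns <- grid$n_shells
  conc <- cbind(p = rep_len(p, ns), d = rep_len(d, ns), n = rep_len(n, ns))
  st <- list(time = time, conc = conc)
  class(st) <- "spheroid_state"
  validate_state(st, grid)
  st
}

validate_state <- function(state, grid = NULL, tol = 1e-9) {
  conc <- state$conc
  if (!is.matrix(conc) || ncol(conc) != 3L)
    stop("state$conc must be an n x 3 matrix (columns p, d, n)")
  if (!is.null(grid) && nrow(conc) != grid$n_shells)
    stop("state and grid have different numbers of shells")
  if (any(conc < -tol) || any(conc > 1 + tol))
    stop("concentrations must lie in [0, 1]")
  if (any(rowSums(conc) > 1 + tol))
    stop("per-shell total concentration exceeds 1")
  invisible(state)
}

#' @export
print.spheroid_state <- function(x, ...) {
  occ <- which(rowSums(x$conc) > 0)
  cat(sprintf("<spheroid_state> t = %.4g h, %d shells (%d occupied)\n",
              x$time, nrow(x$conc), length(occ)))
  invisible(x)
}

#' Extend a grid so the spheroid never touches the outer boundary
#'
#' If the total concentration in the outermost shell exceeds `threshold`,
#' appends `chunk` empty shells (state padded with zeros); otherwise returns
#' the inputs unchanged. Total cell volume is exactly preserved.
#'
#' @param grid a [shell_grid()].
#' @param state a matching [spheroid_state()].
#' @param chunk number of shells to append when growth is needed.
#' @param threshold outermost-shell total concentration that triggers growth.
#' @return A list with elements `grid` and `state`.
#' @export
extend_grid <- function(grid, state, chunk = 8L, threshold = 1e-6) {
  stopifnot(inherits(grid, "shell_grid"), inherits(state, "spheroid_state"))
  if (nrow(state$conc) != grid$n_shells)
    stop("state and grid have different numbers of shells")
  last <- grid$n_shells
  if (sum(state$conc[last, ]) <= threshold)
    return(list(grid = grid, state = state))
  g2 <- shell_grid(grid$dr, grid$n_shells + as.integer(chunk))
  pad <- matrix(0, as.integer(chunk), 3,
                dimnames = list(NULL, c("p", "d", "n")))
  st2 <- state
  st2$conc <- rbind(state$conc, pad)
  list(grid = g2, state = st2)
}
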