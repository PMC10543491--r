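CORNERS <- rbind("E(0,0)" = c(0, 0), "S(0,1)" = c(0, 1),
                 "N(1,0)" = c(1, 0), "K(1,1)" = c(1, 1))

#' Solver configuration for the replicator integrator
#'
#' The dynamics are integrated with classical fixed-step RK4. Defaults:
#' `dt = 0.01` time units, up to `max_steps = 1e5` steps, convergence
#' declared within `convergence_tol = 1e-3` (euclidean) of a corner, and
#' an interior stall declared when the velocity norm drops below
#' `stall_tol = 1e-10` away from any corner (e.g. when started exactly on
#' the interior saddle).
#'
#' @param dt step size (time units), > 0.
#' @param max_steps maximum number of RK4 steps, >= 1.
#' @param convergence_tol distance to a corner at which the trajectory is
#'   declared converged; must be positive and < 0.5 so the corner is
#'   unique.
#' @param stall_tol velocity-norm threshold for interior stalls, > 0.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(dt = 0.01, max_steps = 100000L,
                          convergence_tol = 1e-3, stall_tol = 1e-10) {
  stopifnot(dt > 0, max_steps >= 1, convergence_tol > 0, stall_tol > 0)
  if (convergence_tol >= 0.5) {
    stop("convergence_tol must be < 0.5: two corners could match", call. = FALSE)
  }
  structure(list(dt = dt, max_steps = as.integer(max_steps),
                 convergence_tol = convergence_tol, stall_tol = stall_tol),
            class = "solver_config")
}

#' Integrate the replicator dynamics from an initial state
#'
#' Runs fixed-step RK4 on the replicator system from an interior initial
#' condition until the trajectory comes within `convergence_tol` of a
#' corner, the velocity stalls in the interior, or `max_steps` is
#' exhausted. States are clamped to the unit square after each step; the
#' scheme is accurate enough that the clamping magnitude stays below
#' 1e-9 -- if it does not, an error advises a smaller `dt`.
#'
#' @param p a `game_params` object.
#' @param init numeric length-2 initial state `(x0, y0)`, strictly inside
#'   the open square `(0,1)^2`.
#' @param config a [solver_config()].
#' @param record_every record every k-th step in the returned trajectory
#'   (the initial and final states are always kept); `0` records only the
#'   endpoints.
#' @return list of class `game_trajectory` with fields `times`, `x`, `y`,
#'   `final`, `status` (`"converged"`, `"stalled"` or `"max-steps"`),
#'   `corner` (name and coordinates when converged, else `NULL`), `steps`
#'   and `max_clamp`.
#' @examples
#' tr <- integrate_replicator(baseline_params(), c(0.5, 0.5))
#' tr$corner  # the collusion corner K(1,1)
#' @export
integrate_replicator <- function(p, init = c(0.5, 0.5),
                                 config = solver_config(),
                                 record_every = 10L) {
  stopifnot(inherits(p, "game_params"), inherits(config, "solver_config"),
            is.numeric(init), length(init) == 2L)
  if (any(init <= 0) || any(init >= 1)) {
    stop("initial state must lie strictly inside (0,1)^2", call. = FALSE)
  }
  cv <- condition_values(p)
  r <- rk4_replicator(cv[["A1"]], cv[["B1"]], cv[["A2"]], cv[["B2"]],
                      init[1], init[2], config$dt, config$max_steps,
                      config$convergence_tol, config$stall_tol,
                      as.integer(record_every))
  if (r$status == 3L) {
    stop(sprintf(paste0("integration accuracy error: clamping magnitude %g ",
                        "exceeds 1e-9; reduce dt (currently %g)"),
                 r$max_clamp, config$dt), call. = FALSE)
  }
  if (r$status == 4L) stop("integration produced a non-finite state", call. = FALSE)
  status <- c("converged", "stalled", "max-steps")[r$status + 1L]
  corner <- if (r$corner > 0L) {
    structure(CORNERS[r$corner, ], names = c("x", "y"),
              label = rownames(CORNERS)[r$corner])
  } else NULL
  structure(list(times = r$times, x = r$x, y = r$y,
                 final = c(x = r$final[1], y = r$final[2]),
                 status = status, corner = corner, steps = r$steps,
                 max_clamp = r$max_clamp, params = p, config = config),
            class = "game_trajectory")
}

#' Identify the corner a trajectory converged to
#'
#' @param traj a `game_trajectory`, or a numeric length-2 final state.
#' @param tol distance threshold; must be < 0.5 so at most one corner can
#'   match.
#' @return the corner coordinates (named numeric, with a `label`
#'   attribute), or `NULL` when no corner is within `tol`.
#' @examples
#' detect_convergence(c(0.9995, 0.9992), tol = 1e-2)
#' @export
detect_convergence <- function(traj, tol = 1e-3) {
  if (tol >= 0.5) {
    stop("ambiguous tolerance: tol >= 0.5 could match two corners", call. = FALSE)
  }
  state <- if (inherits(traj, "game_trajectory")) traj$final
    else if (is.numeric(traj) && length(traj) == 2L) traj
    else stop("traj must be a game_trajectory or a length-2 state", call. = FALSE)
  d2 <- (CORNERS[, 1] - state[1])^2 + (CORNERS[, 2] - state[2])^2
  i <- which.min(d2)
  if (d2[i] <= tol^2) {
    structure(CORNERS[i, ], names = c("x", "y"), label = rownames(CORNERS)[i])
  } else NULL
}

#' Map basins of attraction over a grid of initial conditions
#'
#' Integrates the dynamics from an `n x n` uniform grid of interior
#' initial conditions (the exact boundary is excluded: the edges of the
#' square are invariant lines and would bias the fractions) and reports
#' the fraction of initial conditions captured by each corner.
#'
#' @param p a `game_params` object.
#' @param n grid resolution per axis, >= 3.
#' @param config a [solver_config()].
#' @return list of class `basin_summary` with fields `n`, `fractions`
#'   (named vector over the four corners plus `unresolved`, summing to 1),
#'   `counts`, `grid` (data frame of `x0`, `y0`, `corner`, `steps`).
#' @examples
#' \donttest{
#' basin_map(baseline_params(), n = 11)
#' }
#' @export
basin_map <- function(p, n = 21, config = solver_config()) {
  stopifnot(inherits(p, "game_params"), n >= 3)
  g <- seq_len(n) / (n + 1)
  grid <- expand.grid(x0 = g, y0 = g)
  cv <- condition_values(p)
  r <- rk4_basin(cv[["A1"]], cv[["B1"]], cv[["A2"]], cv[["B2"]],
                 grid$x0, grid$y0, config$dt, config$max_steps,
                 config$convergence_tol, config$stall_tol)
  if (any(r$status == 3L)) {
    i <- which(r$status == 3L)[1]
    stop(sprintf(paste0("integration accuracy error from initial condition ",
                        "(%g, %g); reduce dt"), grid$x0[i], grid$y0[i]),
         call. = FALSE)
  }
  if (any(r$status == 4L)) {
    i <- which(r$status == 4L)[1]
    stop(sprintf("non-finite state from initial condition (%g, %g)",
                 grid$x0[i], grid$y0[i]), call. = FALSE)
  }
  lab <- c("unresolved", rownames(CORNERS))[r$corner + 1L]
  counts <- vapply(c(rownames(CORNERS), "unresolved"),
                   function(k) sum(lab == k), integer(1))
  structure(list(n = n, fractions = counts / nrow(grid), counts = counts,
                 grid = data.frame(grid, corner = lab, steps = r$steps),
                 config = config),
            class = "basin_summary")
}

#' @export
print.game_trajectory <- function(x, ...) {
  cat(sprintf("Replicator trajectory: %d steps (dt = %g), status: %s\n",
              x$steps, x$config$dt, x$status))
  if (!is.null(x$corner)) {
    cat(sprintf("  converged to %s\n", attr(x$corner, "label")))
  }
  cat(sprintf("  final state (%.6f, %.6f), max clamp %.3g\n",
              x$final[1], x$final[2], x$max_clamp))
  invisible(x)
}

#' @export
plot.game_trajectory <- function(x, ...) {
  matplot(x$times, cbind(x$x, x$y), type = "l", lty = 1, lwd = 2,
          col = c("firebrick", "steelblue"), xlab = "time",
          ylab = "fraud frequency", ylim = c(0, 1), ...)
  legend("right", c("doctors (x)", "patients (y)"), lty = 1, lwd = 2,
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' @export
print.basin_summary <- function(x, ...) {
  cat(sprintf("Basin map on a %d x %d interior grid:\n", x$n, x$n))
  print(round(x$fractions, 4))
  invisible(x)
}
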