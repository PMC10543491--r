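#' Specify a single-parameter sweep experiment
#'
#' A sweep integrates the dynamics once per value of one model parameter,
#' holding every other parameter at `base` and starting each run from the
#' common initial state (default `(0.5, 0.5)`, the uninformative prior
#' over strategies).
#'
#' @param param name of the swept parameter (one of [param_names()]).
#' @param values non-empty numeric vector of values to sweep over.
#' @param base a `game_params` object supplying the held-fixed values.
#' @param init common initial state for every run.
#' @param config a [solver_config()].
#' @param allow_boundary passed to [validate_params()]; lets `f` or `g`
#'   take the value 0 (used by the built-in moral-hazard sweeps).
#' @return list of class `sweep_spec`.
#' @export
sweep_spec <- function(param, values, base = baseline_params(),
                       init = c(0.5, 0.5), config = solver_config(),
                       allow_boundary = FALSE) {
  stopifnot(inherits(base, "game_params"))
  if (!param %in% param_names()) {
    stop("unknown sweep parameter: ", param, call. = FALSE)
  }
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  structure(list(param = param, values = as.numeric(values), base = base,
                 init = init, config = config,
                 allow_boundary = isTRUE(allow_boundary)),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' For each swept value: re-validate the parameter set (an invalid value
#' is recorded as such, not fatal), classify the regime, locate the
#' interior equilibrium and area-rule prediction where applicable, and
#' integrate the dynamics from the common initial state.
#'
#' @param spec a [sweep_spec()].
#' @return a data frame of class `fraud_sweep`, one row per swept value,
#'   with columns `param`, `value`, `valid`, `case_id`, `x_star`,
#'   `y_star`, `area_PSEN`, `predicted`, `terminal_x`, `terminal_y`,
#'   `steps`, `status`. The full trajectories are attached as the
#'   `"trajectories"` attribute (a named list).
#' @examples
#' sw <- run_sweep(sweep_spec("C1", c(3, 5, 7)))
#' sw[, c("value", "terminal_x", "steps")]
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$values))
  trajs <- vector("list", length(spec$values))
  n_valid <- 0L
  for (i in seq_along(spec$values)) {
    v <- spec$values[i]
    row <- data.frame(param = spec$param, value = v, valid = FALSE,
                      case_id = NA_character_, x_star = NA_real_,
                      y_star = NA_real_, area_PSEN = NA_real_,
                      predicted = NA_character_, terminal_x = NA_real_,
                      terminal_y = NA_real_, steps = NA_integer_,
                      status = NA_character_, stringsAsFactors = FALSE)
    pv <- tryCatch(
      do.call(update_params,
              c(list(spec$base), stats::setNames(list(v), spec$param),
                list(allow_boundary = spec$allow_boundary))),
      error = function(e) NULL)
    if (!is.null(pv)) {
      n_valid <- n_valid + 1L
      row$valid <- TRUE
      cl <- classify_case(pv)
      row$case_id <- cl$case_id
      ie <- interior_equilibrium(pv)
      row$x_star <- ie$x_star
      row$y_star <- ie$y_star
      if (cl$case_id == "case3") {
        att <- predict_attractor(pv)
        row$area_PSEN <- att$area_PSEN
        row$predicted <- att$predicted
      }
      tr <- integrate_replicator(pv, init = spec$init, config = spec$config)
      row$terminal_x <- unname(tr$final[1])
      row$terminal_y <- unname(tr$final[2])
      row$steps <- tr$steps
      row$status <- tr$status
      trajs[[i]] <- tr
    }
    rows[[i]] <- row
  }
  if (n_valid == 0L) {
    stop("sweep specification error: every swept value is invalid", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  names(trajs) <- paste0(spec$param, "=", spec$values)
  attr(out, "trajectories") <- trajs
  attr(out, "spec") <- spec
  class(out) <- c("fraud_sweep", class(out))
  out
}

#' Built-in sweep experiments of the numerical study
#'
#' The nine scripted sweeps over the baseline parameter set, one per
#' simulation panel: doctor fraud cost `C1` in 3..7, patient fraud cost
#' `C2` in 2..4, doctor moral hazard `f` down from 0.8 to 0, patient
#' moral hazard `g` down from 0.6 to 0, penalties `P1` in 5..7 and `P2`
#' in 3..7, rewards `R1` in 5..9 and `R2` in 3..7, and the bribe `H` in
#' 2..6. The moral-hazard lists include the endpoint 0, so those two
#' specs are built with `allow_boundary = TRUE`.
#'
#' @param config a [solver_config()] shared by all specs.
#' @return named list of [sweep_spec()] objects: `fig6_doctor`,
#'   `fig6_patient`, `fig7_doctor`, `fig7_patient`, `fig8_doctor`,
#'   `fig8_patient`, `fig9_doctor`, `fig9_patient`, `fig10`.
#' @examples
#' names(builtin_figures())
#' @export
builtin_figures <- function(config = solver_config()) {
  base <- baseline_params()
  sp <- function(param, values, allow_boundary = FALSE) {
    sweep_spec(param, values, base = base, config = config,
               allow_boundary = allow_boundary)
  }
  list(
    fig6_doctor  = sp("C1", c(3, 4, 5, 6, 7)),
    fig6_patient = sp("C2", c(2, 2.5, 3, 3.5, 4)),
    fig7_doctor  = sp("f", c(0.8, 0.6, 0.4, 0.2, 0), allow_boundary = TRUE),
    fig7_patient = sp("g", c(0.6, 0.5, 0.4, 0.3, 0), allow_boundary = TRUE),
    fig8_doctor  = sp("P1", c(5, 5.5, 6, 6.5, 7)),
    fig8_patient = sp("P2", c(3, 4, 5, 6, 7)),
    fig9_doctor  = sp("R1", c(5, 6, 7, 8, 9)),
    fig9_patient = sp("R2", c(3, 4, 5, 6, 7)),
    fig10        = sp("H", c(2, 3, 4, 5, 6)))
}

#' @export
plot.fraud_sweep <- function(x, coord = c("x", "y"), ...) {
  coord <- match.arg(coord)
  trajs <- attr(x, "trajectories")
  trajs <- trajs[!vapply(trajs, is.null, logical(1))]
  if (length(trajs) == 0L) stop("no trajectories recorded", call. = FALSE)
  cols <- grDevices::hcl.colors(length(trajs), "Zissou 1")
  tmax <- max(vapply(trajs, function(tr) max(tr$times), numeric(1)))
  plot(NA, xlim = c(0, tmax), ylim = c(0, 1), xlab = "time",
       ylab = paste0("fraud frequency (", coord, ")"), ...)
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    graphics::lines(tr$times, if (coord == "x") tr$x else tr$y,
                    col = cols[i], lwd = 2)
  }
  legend("right", names(trajs), col = cols, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
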