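#' Interior (mixed-strategy) equilibrium of the replicator system
#'
#' Solves `-A1 + y B1 = 0` and `-A2 + x B2 = 0` for the interior rest
#' point `(x* , y*) = (A2/B2, A1/B1)`. The point is a bona-fide fifth
#' equilibrium of the game only when both coordinates lie strictly inside
#' `(0, 1)`; otherwise (or when a denominator vanishes) it is reported as
#' absent, with the condition values still attached.
#'
#' @param p a `game_params` object.
#' @param tol tolerance used for the strict-interior test.
#' @return list of class `interior_equilibrium` with fields `exists`,
#'   `degenerate` (a denominator is numerically zero), `x_star`, `y_star`
#'   (NA when degenerate) and the condition values `A1, B1, A2, B2`.
#' @examples
#' interior_equilibrium(baseline_params())  # x* ~ 0.4177, y* ~ 0.4835
#' @export
interior_equilibrium <- function(p, tol = 1e-9) {
  cv <- condition_values(p)
  degenerate <- abs(cv[["B1"]]) <= tol || abs(cv[["B2"]]) <= tol
  x_star <- if (abs(cv[["B2"]]) > tol) cv[["A2"]] / cv[["B2"]] else NA_real_
  y_star <- if (abs(cv[["B1"]]) > tol) cv[["A1"]] / cv[["B1"]] else NA_real_
  exists <- !degenerate &&
    x_star > tol && x_star < 1 - tol &&
    y_star > tol && y_star < 1 - tol
  structure(list(exists = exists, degenerate = degenerate,
                 x_star = x_star, y_star = y_star,
                 A1 = cv[["A1"]], B1 = cv[["B1"]],
                 A2 = cv[["A2"]], B2 = cv[["B2"]]),
            class = "interior_equilibrium")
}

#' Enumerate the equilibria of the game
#'
#' The four corners of the unit square -- `E(0,0)`, `S(0,1)`, `N(1,0)`,
#' `K(1,1)` -- are rest points for every parameter set; the interior point
#' `P(x*, y*)` is included when it lies strictly inside the square.
#'
#' @inheritParams interior_equilibrium
#' @return a numeric matrix with columns `x`, `y` and 4 or 5 rows named
#'   `E`, `S`, `N`, `K` (and `P` when present).
#' @examples
#' enumerate_equilibria(baseline_params())  # 5 points (bistable regime)
#' @export
enumerate_equilibria <- function(p, tol = 1e-9) {
  pts <- rbind(E = c(0, 0), S = c(0, 1), N = c(1, 0), K = c(1, 1))
  ie <- interior_equilibrium(p, tol = tol)
  if (ie$exists) pts <- rbind(pts, P = c(ie$x_star, ie$y_star))
  colnames(pts) <- c("x", "y")
  pts
}

#' Jacobian of the replicator vector field
#'
#' Analytic Jacobian of `(F, G)` with respect to `(x, y)`:
#' \deqn{\partial F/\partial x = (1-2x)(-A_1 + y B_1), \quad
#'       \partial F/\partial y = x(1-x) B_1,}
#' \deqn{\partial G/\partial x = y(1-y) B_2, \quad
#'       \partial G/\partial y = (1-2y)(-A_2 + x B_2).}
#'
#' @inheritParams utilities
#' @return a `2 x 2` numeric matrix, rows `(F, G)`, columns `(x, y)`.
#' @examples
#' jacobian(baseline_params(), 0, 0)  # diag(-4.4, -3.3)
#' @export
jacobian <- function(p, x, y) {
  stopifnot(length(x) == 1L, length(y) == 1L,
            x >= 0, x <= 1, y >= 0, y <= 1)
  cv <- condition_values(p)
  matrix(c((1 - 2 * x) * (-cv[["A1"]] + y * cv[["B1"]]),
           y * (1 - y) * cv[["B2"]],
           x * (1 - x) * cv[["B1"]],
           (1 - 2 * y) * (-cv[["A2"]] + x * cv[["B2"]])),
         nrow = 2, dimnames = list(c("F", "G"), c("x", "y")))
}

#' Classify the stability of an equilibrium point
#'
#' Applies the planar determinant/trace criterion to the Jacobian at an
#' equilibrium: `det > 0, trace < 0` is asymptotically stable (an ESS of
#' the game); `det > 0, trace > 0` is unstable; `det < 0` is a saddle
#' regardless of the trace; `det > 0, trace = 0` is treated as a saddle
#' (the convention used for the degenerate interior point, whose trace is
#' identically zero); `det = 0` is indeterminate. Sign tests use the
#' tolerance `tol`.
#'
#' @param p a `game_params` object.
#' @param point numeric length-2 vector `(x, y)`; must be an equilibrium.
#' @param tol tolerance for the det/trace sign tests.
#' @param eq_tol tolerance for the equilibrium precondition on
#'   `||(F, G)||`.
#' @return list of class `equilibrium_report` with fields `point`,
#'   `jacobian`, `det`, `trace` and
#'   `label` in `{"ESS", "unstable", "saddle", "indeterminate"}`.
#' @examples
#' classify_point(baseline_params(), c(0, 0))$label  # "ESS"
#' @export
classify_point <- function(p, point, tol = 1e-9, eq_tol = 1e-8) {
  stopifnot(is.numeric(point), length(point) == 2L)
  v <- replicator_rhs(p, point[1], point[2])
  speed <- sqrt(v$F^2 + v$G^2)
  if (speed > eq_tol) {
    stop(sprintf("point (%g, %g) is not an equilibrium: |rhs| = %g",
                 point[1], point[2], speed), call. = FALSE)
  }
  J <- jacobian(p, point[1], point[2])
  d <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  tr <- J[1, 1] + J[2, 2]
  label <- if (abs(d) <= tol) "indeterminate"
    else if (d < 0) "saddle"
    else if (tr < -tol) "ESS"
    else if (tr > tol) "unstable"
    else "saddle"
  structure(list(point = c(x = point[1], y = point[2]), jacobian = J,
                 det = d, trace = tr, label = label),
            class = "equilibrium_report")
}

#' Identify the parameter regime (case 1, 2 or 3)
#'
#' The inequality systems on the condition values `A1, B1, A2, B2`
#' delimit three qualitative regimes:
#'
#' * `case1`: `0 < B2 < A2` and `0 < B1 < A1` (formally `x* > 1`,
#'   `y* > 1`) -- honesty dominates; `E(0,0)` is the unique ESS.
#' * `case2`: `A2 < 0 < B2` and `A1 < 0 < B1` (`x* < 0`, `y* < 0`) --
#'   fraud dominates; `K(1,1)` is the unique ESS.
#' * `case3`: `0 < A2 < B2` and `0 < A1 < B1` (`0 < x*, y* < 1`) --
#'   bistable; `E` and `K` are both ESS, separated by the interior saddle.
#'
#' Parameter sets on or outside these (strict, tolerance-`tol`) systems
#' are labelled `other`.
#'
#' @inheritParams interior_equilibrium
#' @return list of class `case_label` with fields `case_id` in
#'   `{"case1", "case2", "case3", "other"}` and `A1, B1, A2, B2`.
#' @examples
#' classify_case(baseline_params())$case_id  # "case3"
#' @export
classify_case <- function(p, tol = 1e-9) {
  cv <- condition_values(p)
  A1 <- cv[["A1"]]; B1 <- cv[["B1"]]; A2 <- cv[["A2"]]; B2 <- cv[["B2"]]
  case_id <-
    if (B2 > tol && A2 - B2 > tol && B1 > tol && A1 - B1 > tol) "case1"
    else if (A2 < -tol && B2 > tol && A1 < -tol && B1 > tol) "case2"
    else if (A2 > tol && B2 - A2 > tol && A1 > tol && B1 - A1 > tol) "case3"
    else "other"
  structure(list(case_id = case_id, A1 = A1, B1 = B1, A2 = A2, B2 = B2),
            class = "case_label")
}

#' Predict the long-run attractor in the bistable regime
#'
#' In the bistable regime the unit square is split by the interior saddle
#' `P(x*, y*)` into two basins whose areas are approximated by the two
#' quadrilaterals with vertices `S(0,1), E(0,0), N(1,0), P` (shoelace area
#' `(x* + y*)/2`, the basin of the non-fraud corner `E`) and
#' `S, K(1,1), N, P` (the complement). The corner with the larger
#' quadrilateral is predicted to capture the population: `K(1,1)` when
#' `(x* + y*)/2 < 1/2`, `E(0,0)` when `> 1/2`, and `undetermined` at
#' equality (within `tol`).
#'
#' @inheritParams interior_equilibrium
#' @return list of class `attractor_prediction` with fields `predicted`
#'   (`"E(0,0)"`, `"K(1,1)"` or `"undetermined"`), `corner` (length-2
#'   numeric, or `NULL` when undetermined), `area_PSEN` and `area_PSKN`.
#' @examples
#' predict_attractor(baseline_params())  # area_PSEN ~ 0.4506 -> K(1,1)
#' @export
predict_attractor <- function(p, tol = 1e-9) {
  cl <- classify_case(p, tol = tol)
  if (cl$case_id != "case3") {
    stop("attractor prediction requires the bistable regime (case3); got ",
         cl$case_id, call. = FALSE)
  }
  ie <- interior_equilibrium(p, tol = tol)
  area_psen <- (ie$x_star + ie$y_star) / 2
  area_pskn <- 1 - area_psen
  if (abs(area_psen - 0.5) <= tol) {
    predicted <- "undetermined"; corner <- NULL
  } else if (area_psen < 0.5) {
    predicted <- "K(1,1)"; corner <- c(1, 1)
  } else {
    predicted <- "E(0,0)"; corner <- c(0, 0)
  }
  structure(list(predicted = predicted, corner = corner,
                 area_PSEN = area_psen, area_PSKN = area_pskn,
                 x_star = ie$x_star, y_star = ie$y_star),
            class = "attractor_prediction")
}

#' Full equilibrium-and-stability report for a parameter set
#'
#' Convenience wrapper: regime label, every equilibrium with its Jacobian
#' determinant, trace and stability label, and (in the bistable regime)
#' the area-rule attractor prediction.
#'
#' @inheritParams interior_equilibrium
#' @return list of class `game_analysis` with fields `params`, `case`,
#'   `equilibria` (named list of `equilibrium_report`) and `attractor`
#'   (`NULL` outside case 3).
#' @export
analyze_game <- function(p, tol = 1e-9) {
  cl <- classify_case(p, tol = tol)
  pts <- enumerate_equilibria(p, tol = tol)
  reports <- lapply(rownames(pts), function(nm) {
    classify_point(p, pts[nm, ], tol = tol)
  })
  names(reports) <- rownames(pts)
  att <- if (cl$case_id == "case3") predict_attractor(p, tol = tol) else NULL
  structure(list(params = p, case = cl, equilibria = reports,
                 attractor = att),
            class = "game_analysis")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("Equilibrium (%g, %g): det = %.6g, trace = %.6g -> %s\n",
              x$point[1], x$point[2], x$det, x$trace, x$label))
  invisible(x)
}

#' @export
print.case_label <- function(x, ...) {
  cat(sprintf("Regime: %s  (A1 = %.4g, B1 = %.4g, A2 = %.4g, B2 = %.4g)\n",
              x$case_id, x$A1, x$B1, x$A2, x$B2))
  invisible(x)
}

#' @export
print.attractor_prediction <- function(x, ...) {
  cat(sprintf(
    "Saddle at (%.4f, %.4f); area toward E = %.4f, toward K = %.4f -> %s\n",
    x$x_star, x$y_star, x$area_PSEN, x$area_PSKN, x$predicted))
  invisible(x)
}

#' @export
print.game_analysis <- function(x, ...) {
  print(x$case)
  for (r in x$equilibria) print(r)
  if (!is.null(x$attractor)) print(x$attractor)
  invisible(x)
}

#' @export
print.interior_equilibrium <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("Interior equilibrium at (%.5f, %.5f)\n", x$x_star, x$y_star))
  } else {
    cat("No interior equilibrium in (0,1)^2",
        if (x$degenerate) " (degenerate denominator)\n" else "\n", sep = "")
  }
  cat(sprintf("  A1 = %.4g, B1 = %.4g, A2 = %.4g, B2 = %.4g\n",
              x$A1, x$B1, x$A2, x$B2))
  invisible(x)
}
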