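#' Regime condition values of the replicator system
#'
#' The replicator vector field of the game factors as
#' \deqn{dx/dt = x(1-x)(-A_1 + y B_1), \qquad dy/dt = y(1-y)(-A_2 + x B_2),}
#' so the four constants
#' \deqn{A_1 = C_1 - f N_0 - K_1 + P_1 + \beta_1 K_1 + K_0,}
#' \deqn{B_1 = H + \alpha M - R_1 + g K_0 - f N_0,}
#' \deqn{A_2 = C_2 - g K_0 - N_1 + P_2 + \beta_2 N_1 + N_0,}
#' \deqn{B_2 = -H + (1-\alpha) M - R_2 - g K_0 + f N_0}
#' fully determine the phase portrait: the interior equilibrium sits at
#' `(A2/B2, A1/B1)` and the three parameter regimes are inequality systems
#' in these values (see [classify_case()]).
#'
#' @param p a `game_params` object.
#' @return named numeric vector `c(A1, B1, A2, B2)`.
#' @examples
#' condition_values(baseline_params())  # 4.4, 9.1, 3.3, 7.9
#' @export
condition_values <- function(p) {
  stopifnot(inherits(p, "game_params"))
  c(A1 = p$C1 - p$f * p$N0 - p$K1 + p$P1 + p$beta1 * p$K1 + p$K0,
    B1 = p$H + p$alpha * p$M - p$R1 + p$g * p$K0 - p$f * p$N0,
    A2 = p$C2 - p$g * p$K0 - p$N1 + p$P2 + p$beta2 * p$N1 + p$N0,
    B2 = -p$H + (1 - p$alpha) * p$M - p$R2 - p$g * p$K0 + p$f * p$N0)
}

#' Payoff matrix of the doctor-patient fraud game
#'
#' Builds the eight payoffs of the 2x2 asymmetric game. Under mutual fraud
#' (doctor-patient collusion) the doctor nets
#' `-C1 + H + alpha*M + K1 - beta1*K1 - P1` and the patient
#' `-C2 - H + (1-alpha)*M + N1 - beta2*N1 - P2`: the bribe `H` is paid by
#' the patient to the doctor, so it enters the two cells with opposite
#' sign. A lone fraudulent doctor extracts `f*N0` from an honest patient;
#' a lone fraudulent patient extracts `g*K0` from an honest doctor; the
#' honest party facing fraud collects the institutional reward.
#'
#' @param p a `game_params` object.
#' @return a `2 x 2 x 2` numeric array of class `payoff_matrix`, indexed as
#'   `[doctor strategy, patient strategy, role]` with dimnames
#'   `fraud`/`nonfraud` and `doctor`/`patient`.
#' @examples
#' A <- payoff_matrix(baseline_params())
#' A["fraud", "fraud", "doctor"]    # 10.5
#' A["nonfraud", "nonfraud", ]      # (K0, N0) = (2, 2)
#' @export
payoff_matrix <- function(p) {
  stopifnot(inherits(p, "game_params"))
  A <- array(NA_real_, dim = c(2, 2, 2),
             dimnames = list(doctor = c("fraud", "nonfraud"),
                             patient = c("fraud", "nonfraud"),
                             role = c("doctor", "patient")))
  A["fraud", "fraud", "doctor"] <-
    -p$C1 + p$H + p$alpha * p$M + p$K1 - p$beta1 * p$K1 - p$P1
  A["fraud", "fraud", "patient"] <-
    -p$C2 - p$H + (1 - p$alpha) * p$M + p$N1 - p$beta2 * p$N1 - p$P2
  A["fraud", "nonfraud", "doctor"] <-
    -p$C1 + p$f * p$N0 + p$K1 - p$P1 - p$beta1 * p$K1
  A["fraud", "nonfraud", "patient"] <- p$N0 + p$R2 - p$f * p$N0
  A["nonfraud", "fraud", "doctor"] <- p$K0 + p$R1 - p$g * p$K0
  A["nonfraud", "fraud", "patient"] <-
    -p$C2 + p$g * p$K0 - p$P2 - p$beta2 * p$N1 + p$N1
  A["nonfraud", "nonfraud", "doctor"] <- p$K0
  A["nonfraud", "nonfraud", "patient"] <- p$N0
  class(A) <- c("payoff_matrix", class(A))
  A
}

#' Expected utilities under mixed strategy frequencies
#'
#' Given the fraud frequencies `x` (doctors) and `y` (patients), returns
#' the expected payoff of each pure strategy against the opposing
#' population mixture and the population means:
#' `U11`/`U12` for a fraudulent / honest doctor, `U21`/`U22` for a
#' fraudulent / honest patient, and the mixtures
#' `U1bar = x U11 + (1-x) U12`, `U2bar = y U21 + (1-y) U22`.
#'
#' Vectorised over `x` and `y` (recycled to a common length).
#'
#' @param p a `game_params` object.
#' @param x fraction of doctors playing fraud, in `[0, 1]`.
#' @param y fraction of patients playing fraud, in `[0, 1]`.
#' @return a list of class `utility_profile` with numeric components
#'   `U11, U12, U1bar, U21, U22, U2bar`.
#' @examples
#' utilities(baseline_params(), 0.5, 0.5)
#' @export
utilities <- function(p, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  if (any(x < 0 | x > 1 | y < 0 | y > 1, na.rm = TRUE)) {
    stop("strategy frequencies must lie in [0, 1]", call. = FALSE)
  }
  A <- payoff_matrix(p)
  U11 <- y * A["fraud", "fraud", "doctor"] +
    (1 - y) * A["fraud", "nonfraud", "doctor"]
  U12 <- y * A["nonfraud", "fraud", "doctor"] +
    (1 - y) * A["nonfraud", "nonfraud", "doctor"]
  U21 <- x * A["fraud", "fraud", "patient"] +
    (1 - x) * A["nonfraud", "fraud", "patient"]
  U22 <- x * A["fraud", "nonfraud", "patient"] +
    (1 - x) * A["nonfraud", "nonfraud", "patient"]
  structure(list(U11 = U11, U12 = U12, U1bar = x * U11 + (1 - x) * U12,
                 U21 = U21, U22 = U22, U2bar = y * U21 + (1 - y) * U22),
            class = "utility_profile")
}

#' Replicator vector field of the fraud game
#'
#' Rate of change of the fraud frequencies under two-population replicator
#' dynamics: each strategy grows in proportion to its payoff advantage
#' over its own population's mean, giving
#' \deqn{F = dx/dt = x(1-x)\,(U_{11}-U_{12}) = x(1-x)(-A_1 + y B_1),}
#' \deqn{G = dy/dt = y(1-y)\,(U_{21}-U_{22}) = y(1-y)(-A_2 + x B_2).}
#' Note the patient-side bracket depends on the doctors' frequency `x`:
#' whether fraud pays for a patient hinges on how likely the doctor is to
#' collude. Vectorised over `x` and `y`.
#'
#' @inheritParams utilities
#' @return list of class `velocity` with components `F` (dx/dt) and
#'   `G` (dy/dt).
#' @examples
#' replicator_rhs(baseline_params(), 0.5, 0.5)  # F = 0.0375, G = 0.1625
#' @export
replicator_rhs <- function(p, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  if (any(x < 0 | x > 1 | y < 0 | y > 1, na.rm = TRUE)) {
    stop("strategy frequencies must lie in [0, 1]", call. = FALSE)
  }
  cv <- condition_values(p)
  structure(list(F = x * (1 - x) * (-cv[["A1"]] + y * cv[["B1"]]),
                 G = y * (1 - y) * (-cv[["A2"]] + x * cv[["B2"]])),
            class = "velocity")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Payoff matrix (doctor payoff, patient payoff):\n")
  fmt <- function(i, j) sprintf("(%g, %g)", x[i, j, "doctor"], x[i, j, "patient"])
  m <- matrix(c(fmt(1, 1), fmt(1, 2), fmt(2, 1), fmt(2, 2)),
              2, 2, byrow = TRUE,
              dimnames = list(doctor = c("fraud", "nonfraud"),
                              patient = c("fraud", "nonfraud")))
  print(m, quote = FALSE)
  invisible(x)
}
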