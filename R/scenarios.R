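#' Default sampling ranges for synthetic parameter scenarios
#'
#' Uniform boxes bracketing the baseline study values: honest payoffs
#' `K0, N0 ~ U(1, 5)` with fraud payoffs exceeding them by `U(1, 10)`;
#' costs, penalties and rewards `~ U(0, 10)`; bribe `H ~ U(0, 8)`;
#' collusion surplus `M ~ U(5, 40)`; and all unit-interval coefficients
#' `~ U(0.05, 0.95)`. All three regimes have non-negligible acceptance
#' rates under these ranges.
#'
#' @return named list of length-2 numeric ranges; `K1_gap` and `N1_gap`
#'   are the ranges of `K1 - K0` and `N1 - N0`.
#' @export
default_ranges <- function() {
  u01 <- c(0.05, 0.95)
  list(K0 = c(1, 5), N0 = c(1, 5), K1_gap = c(1, 10), N1_gap = c(1, 10),
       C1 = c(0, 10), C2 = c(0, 10), P1 = c(0, 10), P2 = c(0, 10),
       R1 = c(0, 10), R2 = c(0, 10), H = c(0, 8), M = c(5, 40),
       f = u01, g = u01, beta1 = u01, beta2 = u01, alpha = u01)
}

#' Specify a synthetic-scenario draw
#'
#' @param case target regime: `"case1"` (unique non-fraud ESS),
#'   `"case2"` (unique fraud ESS), `"case3"` (bistable), or `"any"`.
#' @param seed integer seed for the draw's private random stream
#'   (`NULL` uses the current stream).
#' @param ranges sampling ranges, as [default_ranges()].
#' @param max_attempts cap on rejection-sampling draws.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(case = c("case3", "case1", "case2", "any"),
                          seed = NULL, ranges = default_ranges(),
                          max_attempts = 100000L) {
  case <- match.arg(case)
  stopifnot(max_attempts >= 1)
  needed <- c(setdiff(param_names(), c("K1", "N1")), "K1_gap", "N1_gap")
  missing <- setdiff(needed, names(ranges))
  if (length(missing) > 0L) {
    stop("ranges missing entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(case = case, seed = seed, ranges = ranges,
                 max_attempts = as.integer(max_attempts)),
            class = "scenario_spec")
}

# Draw a batch of parameter vectors from the ranges; returns a data frame
# with one column per model parameter.
draw_batch <- function(ranges, m) {
  u <- function(nm) runif(m, ranges[[nm]][1], ranges[[nm]][2])
  d <- data.frame(K0 = u("K0"), N0 = u("N0"),
                  C1 = u("C1"), C2 = u("C2"), f = u("f"), g = u("g"),
                  P1 = u("P1"), P2 = u("P2"), R1 = u("R1"), R2 = u("R2"),
                  beta1 = u("beta1"), beta2 = u("beta2"),
                  H = u("H"), M = u("M"), alpha = u("alpha"))
  d$K1 <- d$K0 + u("K1_gap")
  d$N1 <- d$N0 + u("N1_gap")
  d[param_names()]
}

# Vectorised regime label over a batch (same inequalities as
# classify_case, tolerance 1e-9).
batch_case <- function(d, tol = 1e-9) {
  A1 <- d$C1 - d$f * d$N0 - d$K1 + d$P1 + d$beta1 * d$K1 + d$K0
  B1 <- d$H + d$alpha * d$M - d$R1 + d$g * d$K0 - d$f * d$N0
  A2 <- d$C2 - d$g * d$K0 - d$N1 + d$P2 + d$beta2 * d$N1 + d$N0
  B2 <- -d$H + (1 - d$alpha) * d$M - d$R2 - d$g * d$K0 + d$f * d$N0
  out <- rep("other", nrow(d))
  out[B2 > tol & A2 - B2 > tol & B1 > tol & A1 - B1 > tol] <- "case1"
  out[A2 < -tol & B2 > tol & A1 < -tol & B1 > tol] <- "case2"
  out[A2 > tol & B2 - A2 > tol & A1 > tol & B1 - A1 > tol] <- "case3"
  out
}

#' Sample synthetic parameter sets from a target regime
#'
#' Rejection sampling: parameter vectors are drawn uniformly from the
#' spec's box ranges (so every draw satisfies the domain constraints by
#' construction) and kept when their regime label matches the target.
#' The draw uses a private seeded random stream; the global RNG state is
#' left untouched. The returned objects carry `seed` and `attempts`
#' attributes.
#'
#' @param spec a [scenario_spec()].
#' @param n number of parameter sets to return.
#' @return a single `game_params` when `n = 1`, else a list of them.
#' @examples
#' p <- sample_params(scenario_spec("case1", seed = 42))
#' classify_case(p)$case_id
#' @export
sample_params <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 1)
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
  }
  kept <- list()
  attempts <- 0L
  n_hits <- 0L
  while (length(kept) < n) {
    m <- min(max(256L, 4L * (n - length(kept))),
             spec$max_attempts - attempts)
    if (m <= 0L) {
      stop(sprintf(paste0("feasibility error: %d/%d accepted after %d draws ",
                          "(acceptance rate %.3g) for target %s"),
                   length(kept), n, attempts,
                   n_hits / max(attempts, 1L), spec$case), call. = FALSE)
    }
    d <- draw_batch(spec$ranges, m)
    attempts <- attempts + m
    lab <- batch_case(d)
    ok <- if (spec$case == "any") rep(TRUE, m) else lab == spec$case
    n_hits <- n_hits + sum(ok)
    for (i in which(ok)) {
      if (length(kept) >= n) break
      kept[[length(kept) + 1L]] <- validate_params(as.list(d[i, ]))
    }
  }
  kept <- lapply(kept, function(p) {
    attr(p, "seed") <- spec$seed
    attr(p, "attempts") <- attempts
    p
  })
  if (n == 1L) kept[[1L]] else kept
}
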