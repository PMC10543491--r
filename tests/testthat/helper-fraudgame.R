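# Random valid parameter sets (any regime), seeded.
rand_params <- function(n, seed) {
  ps <- sample_params(scenario_spec("any", seed = seed), n = n)
  if (n == 1L) list(ps) else ps
}

# Central finite-difference Jacobian of the replicator field.
fd_jacobian <- function(p, x, y, h = 1e-5) {
  fx <- replicator_rhs(p, x + h, y); bx <- replicator_rhs(p, x - h, y)
  fy <- replicator_rhs(p, x, y + h); by <- replicator_rhs(p, x, y - h)
  matrix(c((fx$F - bx$F) / (2 * h), (fx$G - bx$G) / (2 * h),
           (fy$F - by$F) / (2 * h), (fy$G - by$G) / (2 * h)),
         nrow = 2, dimnames = list(c("F", "G"), c("x", "y")))
}

# Stability label at each corner / interior point, as a named vector.
label_pattern <- function(p) {
  vapply(analyze_game(p)$equilibria, function(r) r$label, character(1))
}

corner_label <- function(traj) {
  if (is.null(traj$corner)) NA_character_ else attr(traj$corner, "label")
}
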