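bp <- baseline_params()

test_that("the interior equilibrium at the baseline sits at (A2/B2, A1/B1)", {
  ie <- interior_equilibrium(bp)
  expect_true(ie$exists)
  expect_equal(c(ie$A1, ie$B1, ie$A2, ie$B2), c(4.4, 9.1, 3.3, 7.9))
  expect_equal(ie$x_star, 3.3 / 7.9)
  expect_equal(ie$y_star, 4.4 / 9.1)
  # fixed-point definition
  v <- replicator_rhs(bp, ie$x_star, ie$y_star)
  expect_lt(abs(v$F) + abs(v$G), 1e-10)
})

test_that("the interior point is absent outside the unit square or when degenerate", {
  # honesty-dominant regime: x*, y* > 1
  p1 <- update_params(bp, C1 = 30, C2 = 30)
  ie1 <- interior_equilibrium(p1)
  expect_false(ie1$exists)
  expect_gt(ie1$x_star, 1)
  expect_gt(ie1$y_star, 1)
  # B1 = 0 exactly (R1 chosen to cancel the doctor bracket slope)
  pd <- update_params(bp, R1 = 14.1)
  ied <- interior_equilibrium(pd)
  expect_true(ied$degenerate)
  expect_false(ied$exists)
  expect_true(is.na(ied$y_star))
})

test_that("equilibrium enumeration yields the corners plus a strict-interior point", {
  pts <- enumerate_equilibria(bp)
  expect_equal(nrow(pts), 5L)
  expect_equal(rownames(pts), c("E", "S", "N", "K", "P"))
  expect_equal(unname(pts["P", ]), c(3.3 / 7.9, 4.4 / 9.1))
  expect_equal(nrow(enumerate_equilibria(update_params(bp, C1 = 30, C2 = 30))), 4L)
  expect_equal(nrow(enumerate_equilibria(update_params(bp, R1 = 14.1))), 4L)
})

test_that("analytic Jacobian entries match their closed forms at key states", {
  J0 <- jacobian(bp, 0, 0)
  expect_equal(J0, matrix(c(-4.4, 0, 0, -3.3), 2,
                          dimnames = list(c("F", "G"), c("x", "y"))))
  J1 <- jacobian(bp, 1, 1)
  expect_equal(diag(J1), c(-4.7, -4.6), ignore_attr = TRUE)
  expect_equal(unname(J1[1, 2]), 0)
  # at the centroid both (1-2x) factors vanish; off-diagonals are B/4
  Jc <- jacobian(bp, 0.5, 0.5)
  expect_equal(unname(diag(Jc)), c(0, 0))
  expect_equal(unname(Jc[1, 2]), 9.1 / 4)
  expect_equal(unname(Jc[2, 1]), 7.9 / 4)
})

test_that("the analytic Jacobian agrees with central finite differences", {
  ps <- rand_params(30, seed = 404)
  set.seed(404)
  for (p in ps) {
    x <- runif(1, 0.05, 0.95); y <- runif(1, 0.05, 0.95)
    expect_equal(jacobian(p, x, y), fd_jacobian(p, x, y), tolerance = 1e-6)
  }
})

test_that("stability classification follows the determinant/trace rule", {
  rE <- classify_point(bp, c(0, 0))
  expect_equal(rE$det, 14.52)
  expect_equal(rE$trace, -7.7)
  expect_equal(rE$label, "ESS")
  rS <- classify_point(bp, c(0, 1))
  expect_equal(rS$det, 4.7 * 3.3)
  expect_equal(rS$trace, 8.0)
  expect_equal(rS$label, "unstable")
  ie <- interior_equilibrium(bp)
  rP <- classify_point(bp, c(ie$x_star, ie$y_star))
  expect_lt(rP$det, 0)
  expect_equal(rP$trace, 0)
  expect_equal(rP$label, "saddle")
  # a non-equilibrium state violates the precondition
  expect_error(classify_point(bp, c(0.5, 0.5)), "not an equilibrium")
})

test_that("the zero-determinant degeneracy is labelled indeterminate", {
  # P1 = 0.6 cancels the doctor bracket at y = 0 (A1 = 0), so the
  # Jacobian at E(0,0) is diag(0, -A2) with zero determinant
  p0 <- update_params(bp, P1 = 0.6)
  expect_equal(unname(condition_values(p0)[["A1"]]), 0)
  expect_equal(classify_point(p0, c(0, 0))$label, "indeterminate")
})

test_that("the three inequality regimes are recognised with their condition values", {
  expect_equal(classify_case(bp)$case_id, "case3")
  c1 <- classify_case(update_params(bp, C1 = 30, C2 = 30))
  expect_equal(c1$case_id, "case1")
  expect_equal(c(c1$A1, c1$A2), c(31.4, 31.3))
  c2 <- classify_case(update_params(bp, P1 = 0, P2 = 0, C1 = 0, C2 = 0))
  expect_equal(c2$case_id, "case2")
  expect_equal(c(c2$A1, c2$A2), c(-3.6, -1.7))
  # boundary (B1 = 0) falls outside all three regimes
  expect_equal(classify_case(update_params(bp, R1 = 14.1))$case_id, "other")
})

test_that("the area rule predicts the attractor from the saddle position", {
  att <- predict_attractor(bp)
  expect_equal(att$area_PSEN, (3.3 / 7.9 + 4.4 / 9.1) / 2)
  expect_equal(att$area_PSEN + att$area_PSKN, 1)
  expect_equal(att$predicted, "K(1,1)")
  att7 <- predict_attractor(update_params(bp, C1 = 7))
  expect_equal(att7$y_star, 8.4 / 9.1)
  expect_gt(att7$area_PSEN, 0.5)
  expect_equal(att7$predicted, "E(0,0)")
  # saddle exactly at the centroid: undetermined
  pc <- update_params(bp, P1 = 5.15, P2 = 3.65)
  ie <- interior_equilibrium(pc)
  expect_equal(c(ie$x_star, ie$y_star), c(0.5, 0.5))
  expect_equal(predict_attractor(pc)$predicted, "undetermined")
  # outside the bistable regime the rule does not apply
  expect_error(predict_attractor(update_params(bp, C1 = 30, C2 = 30)), "case3")
})

test_that("det/trace sign patterns match the per-regime stability census", {
  pat3 <- c(E = "ESS", S = "unstable", N = "unstable", K = "ESS", P = "saddle")
  for (p in sample_params(scenario_spec("case3", seed = 405), n = 200)) {
    expect_equal(label_pattern(p), pat3)
  }
  pat1 <- c(E = "ESS", S = "saddle", N = "saddle", K = "unstable")
  for (p in sample_params(scenario_spec("case1", seed = 406), n = 200)) {
    expect_equal(label_pattern(p), pat1)
  }
  pat2 <- c(E = "unstable", S = "saddle", N = "saddle", K = "ESS")
  for (p in sample_params(scenario_spec("case2", seed = 407), n = 200)) {
    expect_equal(label_pattern(p), pat2)
  }
})
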