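bp <- baseline_params()

test_that("solver configuration rejects unusable settings", {
  expect_error(solver_config(dt = 0), "dt > 0")
  expect_error(solver_config(max_steps = 0))
  expect_error(solver_config(convergence_tol = 0.5), "two corners")
})

test_that("the baseline population converges to collusion from the centroid", {
  tr <- integrate_replicator(bp, c(0.5, 0.5))
  expect_equal(tr$status, "converged")
  expect_equal(corner_label(tr), "K(1,1)")
  expect_equal(as.numeric(tr$corner), c(1, 1))
})

test_that("raising the doctor's fraud cost flips the outcome to honesty", {
  tr <- integrate_replicator(update_params(bp, C1 = 7), c(0.5, 0.5))
  expect_equal(corner_label(tr), "E(0,0)")
})

test_that("starting exactly on the interior saddle stalls", {
  ie <- interior_equilibrium(bp)
  tr <- integrate_replicator(bp, c(ie$x_star, ie$y_star))
  expect_equal(tr$status, "stalled")
  expect_equal(tr$steps, 0L)
})

test_that("initial conditions must be strictly interior", {
  expect_error(integrate_replicator(bp, c(0, 0.5)), "strictly inside")
  expect_error(integrate_replicator(bp, c(0.5, 1)), "strictly inside")
})

test_that("trajectories stay in the unit square with vanishing clamping", {
  for (p in list(bp, update_params(bp, C1 = 7), update_params(bp, H = 6))) {
    tr <- integrate_replicator(p, c(0.3, 0.8), record_every = 1L)
    expect_true(all(tr$x >= 0 & tr$x <= 1))
    expect_true(all(tr$y >= 0 & tr$y <= 1))
    expect_true(all(diff(tr$times) > 0))
    expect_lt(tr$max_clamp, 1e-9)
  }
})

test_that("corner detection returns the unique nearby corner or nothing", {
  expect_equal(attr(detect_convergence(c(0.9995, 0.9992), tol = 1e-2), "label"),
               "K(1,1)")
  expect_equal(attr(detect_convergence(c(3e-4, 1e-4), tol = 1e-2), "label"),
               "E(0,0)")
  expect_null(detect_convergence(c(0.5, 0.5), tol = 1e-2))
  expect_error(detect_convergence(c(0.5, 0.5), tol = 0.5), "ambiguous")
  tr <- integrate_replicator(bp, c(0.5, 0.5))
  expect_equal(attr(detect_convergence(tr, tol = 1e-2), "label"), "K(1,1)")
})

test_that("the fixed-step scheme matches an independent RK4 integration", {
  skip_if_not_installed("deSolve")
  cfg <- solver_config(dt = 0.01, max_steps = 100L)
  tr <- integrate_replicator(bp, c(0.5, 0.5), config = cfg, record_every = 1L)
  sol <- deSolve::ode(
    y = c(x = 0.5, y = 0.5), times = seq(0, 1, by = 0.01),
    func = function(t, s, parms) {
      v <- replicator_rhs(bp, s[1], s[2])
      list(c(v$F, v$G))
    }, parms = NULL, method = "rk4")
  expect_equal(tr$x, unname(sol[, "x"]), tolerance = 1e-10)
  expect_equal(tr$y, unname(sol[, "y"]), tolerance = 1e-10)
})

test_that("halving the step size never changes the terminal corner", {
  ps <- sample_params(scenario_spec("case3", seed = 408), n = 100)
  for (p in ps) {
    t1 <- integrate_replicator(p, c(0.5, 0.5), record_every = 0L)
    t2 <- integrate_replicator(p, c(0.5, 0.5),
                               config = solver_config(dt = 0.005),
                               record_every = 0L)
    expect_identical(corner_label(t1), corner_label(t2))
  }
})

test_that("single-attractor regimes capture the whole grid of initial conditions", {
  p1 <- sample_params(scenario_spec("case1", seed = 409))
  b1 <- basin_map(p1, n = 11)
  expect_equal(b1$fractions[["E(0,0)"]], 1)
  p2 <- sample_params(scenario_spec("case2", seed = 410))
  b2 <- basin_map(p2, n = 11)
  expect_equal(b2$fractions[["K(1,1)"]], 1)
})

test_that("the baseline basin split tracks the quadrilateral areas", {
  b <- basin_map(bp, n = 21)
  expect_equal(sum(b$fractions), 1, tolerance = 1e-12)
  att <- predict_attractor(bp)
  expect_lt(abs(b$fractions[["K(1,1)"]] - att$area_PSKN), 0.1)
})

test_that("basin share of collusion correlates with the area rule across games", {
  ps <- sample_params(scenario_spec("case3", seed = 411), n = 50)
  frac <- vapply(ps, function(p) basin_map(p, n = 21)$fractions[["K(1,1)"]],
                 numeric(1))
  area <- vapply(ps, function(p) predict_attractor(p)$area_PSKN, numeric(1))
  expect_gt(stats::cor(frac, area, method = "spearman"), 0.9)
})

test_that("the area-rule prediction agrees with simulation away from the margin", {
  ps <- sample_params(scenario_spec("case3", seed = 412), n = 60)
  checked <- 0L; agreed <- 0L
  for (p in ps) {
    att <- predict_attractor(p)
    if (abs(att$area_PSEN - 0.5) <= 0.05) next
    checked <- checked + 1L
    tr <- integrate_replicator(p, c(0.5, 0.5), record_every = 0L)
    if (!is.null(tr$corner) && all(tr$corner == att$corner)) agreed <- agreed + 1L
  }
  expect_gt(checked, 20L)
  expect_gte(agreed / checked, 0.95)
})
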