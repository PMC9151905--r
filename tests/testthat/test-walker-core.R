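# Stance integration, heel-strike map, actuation limits, and the step map.
# Frozen expected values were computed with an independent deSolve (lsodar)
# integration of the same equations at rtol 1e-10 / atol 1e-12.

test_that("stance integration matches the independent ODE oracle", {
  pre <- integrate_stance(walker_state(0.2, -0.21))
  expect_s3_class(pre, "pre_impact_state")
  expect_equal(pre$step_time, 3.715051, tolerance = 1e-6)
  expect_equal(pre$theta_minus, -0.2065591, tolerance = 1e-6)
  expect_equal(pre$thetadot_minus, -0.2162136, tolerance = 1e-6)
  expect_equal(pre$phidot_minus, -0.05518734, tolerance = 1e-5)
  # legitimacy conditions hold at the event
  expect_lte(pre$theta_minus, 0)
  expect_lte(pre$thetadot_minus, 0)
  expect_equal(pre$phi_minus, 2 * pre$theta_minus, tolerance = 1e-8)
  expect_gte(pre$phidot_minus, 2 * pre$thetadot_minus)

  pre2 <- integrate_stance(walker_state(0.3, -0.31))
  expect_equal(pre2$theta_minus, -0.2855380, tolerance = 1e-6)
  expect_equal(pre2$step_time, 3.964790, tolerance = 1e-6)
})

test_that("stance failures are classified by mechanism", {
  # below the slow heel-strike boundary: cannot pass vertical
  slow <- integrate_stance(walker_state(0.3, -0.29))
  expect_s3_class(slow, "stance_failure")
  expect_identical(slow$failure, "stuck_before_vertical")
  # far beyond the fast boundary: falls forward before a legitimate strike
  fast <- integrate_stance(walker_state(0.3, -0.45))
  expect_s3_class(fast, "stance_failure")
  expect_identical(fast$failure, "falls_forward")
})

test_that("stance energy is conserved along every integrated trajectory", {
  states <- fx_wedge_states(200, seed = 7)
  B <- viabwalk:::cpp_stance_batch(states, 1e-10, 1e-12, 50, -pi / 2)
  ok <- B[, "code"] == 0
  expect_gt(sum(ok), 150)
  expect_lt(max(B[ok, "energy_drift"]), 1e-8)
})

test_that("heel-strike map applies the impact relations", {
  pre <- list(theta_minus = -0.3, thetadot_minus = -0.35)
  st <- heelstrike_map(pre, 0.1)
  expect_identical(st[[1]], 0.3)   # exact assignment, not computation
  expect_equal(st[[2]], -0.35 * cos(-0.6) + 0.1 * sin(-0.6), tolerance = 1e-12)
  expect_equal(st[[2]], -0.345332, tolerance = 1e-6)
  st0 <- heelstrike_map(pre, 0)
  expect_lt(abs(st0[[2]] - (-0.288868)), 1e-6)
  # degenerate impact at the origin leaves the rate unchanged
  st3 <- heelstrike_map(list(theta_minus = 0, thetadot_minus = -0.2), 0.5)
  expect_identical(st3[[1]], 0)
  expect_equal(st3[[2]], -0.2, tolerance = 1e-14)
  # swing reset
  expect_equal(attr(st, "phi_plus"), 0.6, tolerance = 1e-14)
  expect_equal(attr(st, "phidot_plus"), (1 - cos(-0.6)) * st[[2]],
               tolerance = 1e-12)
})

test_that("post-impact rate decreases strictly with push-off in the wedge", {
  pre <- list(theta_minus = -0.3, thetadot_minus = -0.35)
  Ps <- seq(0, 0.5, by = 0.05)
  rates <- vapply(Ps, function(P) heelstrike_map(pre, P)[[2]], numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("push-off limits follow the two-branch actuation formulas", {
  lim <- pushoff_limits(list(theta_minus = -pi / 8, thetadot_minus = -0.4))
  expect_equal(lim$p_max, 0.4, tolerance = 1e-12)
  expect_identical(lim$p_min, 0)
  lim2 <- pushoff_limits(list(theta_minus = -1.0, thetadot_minus = -0.4))
  expect_identical(lim2$p_max, Inf)
  expect_equal(lim2$p_min, 0.183063, tolerance = 1e-6)
  # both formulas are linear in the rate
  lim3 <- pushoff_limits(list(theta_minus = -pi / 8, thetadot_minus = 0))
  expect_equal(lim3$p_max, 0)
  lim4 <- pushoff_limits(list(theta_minus = -1.0, thetadot_minus = 0))
  expect_equal(lim4$p_min, 0)
  # at the maximum push-off (shallow branch) the post-impact rate equals the
  # lift-off-limited value thetadot-/cos(2 theta-): the constraint is active
  pre <- list(theta_minus = -0.3, thetadot_minus = -0.35)
  lim5 <- pushoff_limits(pre)
  st <- heelstrike_map(pre, lim5$p_max)
  expect_equal(st[[2]], -0.35 / cos(-0.6), tolerance = 1e-12)
})

test_that("ground-reaction endpoint checks evaluate the margin", {
  expect_true(grf_ok(walker_state(0.3, -0.9))[["start"]])
  expect_false(grf_ok(walker_state(0.3, -1.0))[["start"]])
  expect_true(grf_ok(walker_state(0, 0))[["start"]])
})

test_that("the minimum stance GRF margin occurs at an endpoint", {
  states <- fx_wedge_states(60, seed = 11)
  B <- viabwalk:::cpp_stance_batch(states, 1e-10, 1e-12, 50, -pi / 2)
  ok <- which(B[, "code"] == 0)
  for (i in ok) {
    m_start <- cos(states[i, 1]) - states[i, 2]^2
    m_end <- cos(B[i, "theta_minus"]) - B[i, "thetadot_minus"]^2
    expect_lt(abs(B[i, "min_grf"] - min(m_start, m_end)), 1e-6)
  }
})

test_that("step map composes the stages and records step observables", {
  fp <- fx_gait_at_P(0.05)
  out <- step_map(fp$state, fp$pushoff)
  expect_identical(out$failure, "none")
  # fixed-point identity to solver tolerance
  expect_lt(max(abs(unclass(out$next_state) - unclass(fp$state))), 1e-8)
  # impact identity is an exact assignment
  expect_identical(out$next_state[[1]], -out$pre_impact$theta_minus)
  expect_equal(out$step_length, 2 * sin(out$next_state[[1]]), tolerance = 1e-12)
  expect_equal(out$step_speed, out$step_length / out$step_time,
               tolerance = 1e-12)
  # infeasible push-off is a failure value, not an exception
  bad <- step_map(fp$state, 50)
  expect_identical(bad$failure, "pushoff_infeasible")
})

test_that("the lower actuation limit is admissible (closed interval)", {
  # steep pre-impact: p_min > 0; applying exactly p_min brings the
  # post-impact rate to zero (the lift-off constraint is active), and the
  # admissible interval is closed so p_min itself is not rejected
  pre <- list(theta_minus = -1.0, thetadot_minus = -0.4)
  lim <- pushoff_limits(pre)
  st <- heelstrike_map(pre, lim$p_min)
  expect_equal(st[[2]], 0, tolerance = 1e-12)
  # the shallow branch's upper limit is likewise active at p_max
  pre2 <- list(theta_minus = -0.2, thetadot_minus = -0.25)
  lim2 <- pushoff_limits(pre2)
  st2 <- heelstrike_map(pre2, lim2$p_max)
  expect_equal(st2[[2]], pre2$thetadot_minus / cos(2 * pre2$theta_minus),
               tolerance = 1e-12)
})
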