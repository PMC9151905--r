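# Period-1 gait families: fixed points, continuation, stability, and
# bifurcation detection.

test_that("both period-1 families exist and are separated by step time", {
  s <- seed_fixed_points(0.05)
  expect_gt(s$long$step_time, s$short$step_time)
  expect_lt(s$long$residual, 1e-9)
  expect_lt(s$short$residual, 1e-9)
  expect_true(s$long$pushoff_feasible)
  # the short-period gait is a saddle
  mags <- sort(abs(s$short$eigenvalues))
  expect_lt(mags[1], 1)
  expect_gt(mags[2], 1)
})

test_that("an open-loop-stable gait re-walks itself for 25 steps", {
  fp <- fx_gait_at_P(0.05)
  expect_true(all(abs(fp$eigenvalues) < 1))
  x <- fp$state
  for (k in 1:25) {
    out <- step_map(x, fp$pushoff)
    expect_identical(out$failure, "none")
    x <- out$next_state
  }
  expect_lt(max(abs(unclass(x) - unclass(fp$state))), 1e-8)
})

test_that("eigenvalues vary continuously along the continued branches", {
  for (br in list(fx_branch_long(), fx_branch_short())) {
    pts <- br$points
    expect_gt(nrow(pts), 300)
    expect_lt(max(abs(diff(pts$eig1))), 0.3)
    expect_lt(max(abs(diff(pts$eig2))), 0.3)
    # no branch jumping: the state itself moves smoothly
    expect_lt(max(abs(diff(pts$theta))), 0.02)
    expect_true(all(diff(pts$P) > 0))
  }
})

test_that("the first period doubling and the transcritical crossing are located", {
  bl <- fx_branch_long()
  pd <- bl$bifurcations[bl$bifurcations$kind == "period_doubling", ]
  expect_gte(nrow(pd), 1)
  expect_equal(pd$P[1], 0.13571, tolerance = 5e-5)
  tc <- bl$bifurcations[bl$bifurcations$kind == "transcritical", ]
  expect_identical(nrow(tc), 1L)
  expect_equal(tc$P[1], 0.79478, tolerance = 5e-5)
  expect_equal(tc$speed[1], 0.38301, tolerance = 5e-5)
  # the short branch crosses at the same parameter
  tcs <- fx_branch_short()$bifurcations
  tcs <- tcs[tcs$kind == "transcritical", ]
  expect_equal(tcs$P[1], tc$P[1], tolerance = 1e-4)
})

test_that("speed inversion round-trips through the fixed point", {
  bl <- fx_branch_long()
  for (V in c(0.051, 0.113, 0.23308)) {
    fp <- speed_to_pushoff(bl, V)
    expect_equal(fp$steady_speed, V, tolerance = 1e-8)
  }
  fp <- speed_to_pushoff(bl, 0.23308)
  expect_lt(abs(fp$pushoff - 0.24214), 5e-5)
  expect_error(speed_to_pushoff(bl, 2), "outside")
})

test_that("the families stay separated in scaled coordinates near the origin", {
  bl <- fx_branch_long()$points
  bs <- fx_branch_short()$points
  ctl <- fx_control()
  # compare scaled rates at matched small push-offs
  Ps <- bl$P[bl$P < 0.02]
  Ps <- Ps[Ps %in% bs$P]
  expect_gt(length(Ps), 5)
  dmin <- Inf
  for (P in Ps) {
    a <- bl[bl$P == P, ]; b <- bs[bs$P == P, ]
    sca <- scale_state(a$theta, a$thetadot, control = ctl)
    scb <- scale_state(b$theta, b$thetadot, control = ctl)
    dmin <- min(dmin, abs(sca - scb))
  }
  expect_gt(dmin, 0.05)
})
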