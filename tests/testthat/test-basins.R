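# Basin-of-attraction estimation, area accounting, coverage, and level-curve
# boundary prediction.

test_that("every basin is contained in the kernel", {
  for (b in fx_openloop_basins()[2:3])
    expect_true(all(!b$membership | b$kernel_mask))
  for (b in fx_cover_basins()[3])
    expect_true(all(!b$membership | b$kernel_mask))
})

test_that("the open-loop basin vanishes once the gait loses stability", {
  b288 <- fx_openloop_basins()[[6]]
  expect_equal(b288$area_fraction_of_kernel, 0, tolerance = 1e-9)
})

test_that("open-loop basin membership is robust to terminal-tolerance halving", {
  K <- fx_kernel()
  fp <- fx_gait_at_P(0.05)
  b1 <- estimate_basin(K, open_loop(0.05), fp, stride = c(5L, 4L),
                       term_tol = 0.01)
  b2 <- estimate_basin(K, open_loop(0.05), fp, stride = c(5L, 4L),
                       term_tol = 0.005)
  expect_lt(abs(b1$area_fraction_of_kernel - b2$area_fraction_of_kernel), 0.2)
})

test_that("coverage arithmetic is consistent", {
  basins <- fx_cover_basins()
  cv <- coverage(basins)
  expect_lte(cv$union_fraction, 100 + 1e-9)
  expect_gte(cv$union_fraction, max(cv$fractions))
  # union of a basin with itself is its own fraction
  cv1 <- coverage(basins[c(3, 3)])
  expect_equal(cv1$union_fraction, basins[[3]]$area_fraction_of_kernel,
               tolerance = 1e-9)
  # the diagonal of the overlap matrix reproduces the fractions
  expect_equal(unname(diag(cv$pairwise_overlaps)), unname(cv$fractions),
               tolerance = 1e-9)
})

test_that("level-curve prediction is declined in the slow regime", {
  K <- fx_kernel()
  fp <- fx_gait_at_V(0.016)
  b <- estimate_basin(K, speed_regulated(0.016), fp, stride = c(5L, 4L))
  pred <- predict_regulated_boundaries(b, K)
  expect_true(pred$declined)
})

test_that("fitted basin edges satisfy the level-curve property", {
  K <- fx_kernel()
  b <- fx_cover_basins()[[3]]   # V* = 0.113
  pred <- predict_regulated_boundaries(b, K)
  expect_false(pred$declined)
  # the slow-side constant sits near the short-period saddle's angle (its
  # stable set forms the basin boundary)
  fps <- speed_to_pushoff(fx_branch_short(), 0.113)
  expect_lt(abs(pred$c_left - (-fps$state[[1]])), 0.05)
  # sampling the fitted level curve reproduces the constant pre-impact angle
  lc <- level_curve(K, pred$c_left, n = 15)
  expect_gt(nrow(lc), 5)
  expect_lt(max(lc$residual), 1e-6)
  # prediction against simulation: the slab approximates the basin's slow
  # flank; the estimates track each other at the few-point level
  expect_lt(abs(pred$predicted_fraction - pred$simulated_fraction), 5)
})

test_that("regulated basins have the saturated-slow-trap watershed", {
  # states landing slower than the short-period saddle drift away from the
  # long gait; members' pre-impact angles stay beyond the saddle's
  K <- fx_kernel()
  b <- fx_cover_basins()[[3]]
  fps <- speed_to_pushoff(fx_branch_short(), 0.113)
  thm <- K$theta_minus[b$rows, b$cols][b$membership]
  expect_lt(quantile(thm, 0.999, na.rm = TRUE), -fps$state[[1]] + 0.05)
})
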