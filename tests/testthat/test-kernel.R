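# Viability-kernel estimation: 1-step viability, the difference-inclusion
# image, nested iterates, the unreachable subset, and boundary validation.

test_that("1-step viability combines the wedge and GRF conditions", {
  expect_false(one_step_viable(walker_state(0.3, -0.29)))  # above the slow curve
  expect_true(one_step_viable(walker_state(0.3, -0.31)))
  expect_false(one_step_viable(walker_state(0.3, -0.45)))  # falls forward
})

test_that("the inclusion image is the attainable-rate segment", {
  # shallow branch endpoints from the closed-form impact relations; the start
  # state is chosen to land at the example's pre-impact angle
  st <- walker_state(0.35, -0.355)
  pre <- integrate_stance(st)
  img <- inclusion_image(st)
  expect_equal(img$theta_next, -pre$theta_minus)
  c2 <- cos(2 * pre$theta_minus)
  expect_equal(img$rate_interval,
               c(pre$thetadot_minus / c2, pre$thetadot_minus * c2),
               tolerance = 1e-12)
  # endpoints equal the heel-strike images at the actuation limits
  lim <- pushoff_limits(pre)
  expect_equal(img$rate_interval[2], heelstrike_map(pre, lim$p_min)[[2]],
               tolerance = 1e-12)
  expect_equal(img$rate_interval[1], heelstrike_map(pre, lim$p_max)[[2]],
               tolerance = 1e-12)
  # direct evaluation of the printed shallow-branch example
  expect_equal(c(-0.35 / cos(-0.6), -0.35 * cos(-0.6)),
               c(-0.424070, -0.288868), tolerance = 1e-6)
})

test_that("kernel iterates are nested and converge by removal exhaustion", {
  K <- fx_kernel()
  expect_gt(K$converged_at, 1)
  expect_identical(tail(K$removals, 1), 0L)
  expect_true(all(diff(K$iterate_areas) <= 1e-12))   # nested j-step regions
  expect_true(K$area <= K$v1_area)
  # the kernel occupies most of the 1-step viable region
  expect_gt(100 * K$area_ratio, 90)
})

test_that("kernel interior states keep an admissible step into the kernel", {
  K <- fx_kernel()
  g <- K$grid
  env <- viabwalk:::column_envelopes(K$membership, g)
  ef <- viabwalk:::envelope_functions(env, g)
  idx <- which(K$membership & !is.na(K$theta_next))
  set.seed(3)
  idx <- sample(idx, 1000)
  thn <- K$theta_next[idx]
  olo_n <- omega_low(thn)
  ohi_n <- splinefun(g$theta, K$omhigh, method = "fmm")(pmin(thn, g$theta_max))
  h <- olo_n - ohi_n
  sc_hi <- (K$w_hi[idx] - olo_n) / h
  sc_lo <- ifelse(is.finite(K$w_lo[idx]), (K$w_lo[idx] - olo_n) / h, -Inf)
  ok <- thn <= g$theta_max &
    sc_hi >= ef$lower(thn) + g$dsc / 2 &
    sc_lo <= ef$upper(thn) - g$dsc / 2
  expect_true(all(ok))
})

test_that("grid refinement leaves the kernel area ratio nearly unchanged", {
  v1c <- one_step_viable_region(grid_spec(425, 101))
  Kc <- viability_kernel(v1c)
  Kf <- fx_kernel()     # 850 x 201: refined 2x in both directions
  expect_lt(abs(100 * Kc$area_ratio - 100 * Kf$area_ratio), 1.0)
})

test_that("the unreachable subset has two major components and is transient", {
  K <- fx_kernel()
  U <- fx_unreachable()
  expect_identical(U$n_major_components, 2L)
  expect_gt(100 * U$fraction_of_kernel, 1)
  expect_lt(100 * U$fraction_of_kernel, 4)
  # all period-1 gaits lie in the reachable subset
  for (P in c(0.01, 0.05, 0.1, 0.2)) {
    fp <- fx_gait_at_P(P)
    g <- K$grid
    j <- round(fp$state[[1]] / g$dtheta)
    sc <- (fp$state[[2]] - K$omlow[j]) / (K$omlow[j] - K$omhigh[j])
    i <- round(-sc / g$dsc) + 1L
    expect_false(U$membership[i, j])
  }
  # any unreachable state leaves the set in one step: its image segment does
  # not meet the unreachable cover (images are reachable by definition; check
  # numerically on sampled members)
  g <- K$grid
  idx <- which(U$membership & !is.na(K$theta_next))
  set.seed(5)
  idx <- sample(idx, min(300, length(idx)))
  jn <- pmin(pmax(round(K$theta_next[idx] / g$dtheta), 1L), g$n_theta)
  olo <- K$omlow[jn]; ohi <- K$omhigh[jn]
  sc_hi <- (K$w_hi[idx] - olo) / (olo - ohi)
  # the image's upper end lies inside the cover band (at or below gamma1)
  expect_true(all(sc_hi <= U$gamma1[jn] + g$dsc))
})

test_that("nonviable 1-step states cannot be kept alive by any push-off", {
  # exclusion: repeated best-effort stepping from removed grid points fails
  # or exits the 1-step region within a bounded number of steps
  K <- fx_kernel()
  v1 <- fx_v1()
  g <- K$grid
  removed <- which(v1$membership & !K$membership)
  set.seed(9)
  removed <- sample(removed, min(200, length(removed)))
  env <- viabwalk:::column_envelopes(K$membership, g)
  ef <- viabwalk:::envelope_functions(env, g)
  escaped <- logical(length(removed))
  for (k in seq_along(removed)) {
    idx <- removed[k]
    # best effort: can its inclusion segment reach the kernel?
    thn <- K$theta_next[idx]
    # landings below the first column are boundary-row states striking at
    # vertical (on the slow heel-strike curve): outside the test's domain
    if (is.na(thn) || thn > g$theta_max || thn < g$theta[1]) {
      escaped[k] <- FALSE; next
    }
    olo_n <- omega_low(thn)
    ohi_n <- splinefun(g$theta, K$omhigh, method = "fmm")(thn)
    h <- olo_n - ohi_n
    sc_hi <- (K$w_hi[idx] - olo_n) / h
    sc_lo <- if (is.finite(K$w_lo[idx])) (K$w_lo[idx] - olo_n) / h else -Inf
    # strict interior test: the refitted final envelope can wiggle by about
    # a cell relative to the envelope in force when the point was removed,
    # so escapes are only counted when the segment reaches well inside
    escaped[k] <- sc_hi >= ef$lower(thn) + 1.5 * g$dsc &&
      sc_lo <= ef$upper(thn) - 1.5 * g$dsc
  }
  expect_lt(mean(escaped), 0.02)
})

test_that("preimage counts differ by two across the upper cover boundary", {
  K <- fx_kernel()
  U <- fx_unreachable()
  rep <- critical_curve_check(K, U, n_pairs = 10)
  expect_gte(nrow(rep), 8)
  expect_gte(sum(rep$diff == 2), ceiling(0.9 * nrow(rep)))
  # a point deep inside the reachable kernel has at least one preimage
  fp <- fx_gait_at_P(0.05)
  g <- K$grid
  sc_fp <- viabwalk:::kernel_scale(K, fp$state[[1]], fp$state[[2]])
  pim <- viabwalk:::preimages_p0(K, fp$state[[1]], sc_fp)
  expect_gte(length(pim), 1)
})

test_that("kernel boundaries carry the expected dynamical signatures", {
  K <- fx_kernel()
  rep <- validate_kernel_boundaries(K, n_samples = 20)
  # the lower boundary merges with the fast heel-strike curve
  expect_gt(rep$merge_theta, 0.2)
  expect_lt(rep$merge_theta, 0.45)
  # free lower boundary maps near itself under zero push-off
  expect_lt(median(rep$gamma_b_image_err_cells, na.rm = TRUE), 4)
  # sampled boundary points admit a push-off keeping the walker in the
  # (closed) kernel
  expect_gt(rep$invariance_ok, 0.9)
})
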