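# Wedge boundaries, scaled coordinates, GRF curves, boundary fitting, and
# the column-band Simpson area machinery.

test_that("the slow heel-strike boundary matches its closed form and the dynamics", {
  expect_lt(abs(omega_low(0.3) - (-0.2988762)), 1e-6)
  expect_equal(omega_low(0), 0)
  # bracket test: 1e-4 below the curve passes vertical, 1e-4 above stalls
  for (th in c(0.15, 0.3, 0.5, 0.7)) {
    w <- omega_low(th)
    below <- integrate_stance(walker_state(th, w - 1e-4))
    above <- integrate_stance(walker_state(th, w + 1e-4))
    expect_false(identical(attr(below, "class"), "stance_failure") &&
                   below$failure == "stuck_before_vertical")
    expect_s3_class(above, "stance_failure")
    expect_identical(above$failure, "stuck_before_vertical")
  }
  # agreement with simulation bisection: the classification flips across the
  # closed-form value within 1e-6
  for (th in c(0.2, 0.45, 0.65)) {
    w <- omega_low(th)
    code_in <- integrate_stance(walker_state(th, w - 1e-6))
    code_out <- integrate_stance(walker_state(th, w + 1e-6))
    expect_false(inherits(code_in, "stance_failure") &&
                   code_in$failure == "stuck_before_vertical")
    expect_true(inherits(code_out, "stance_failure"))
  }
})

test_that("the fast heel-strike boundary separates strikes from falls", {
  for (th in c(0.2, 0.4, 0.6)) {
    w <- omega_high(th)
    expect_lt(w, omega_low(th))   # more negative: region orientation
    inside <- integrate_stance(walker_state(th, w + 1e-4))
    outside <- integrate_stance(walker_state(th, w - 1e-4))
    expect_s3_class(inside, "pre_impact_state")
    expect_s3_class(outside, "stance_failure")
    expect_identical(outside$failure, "falls_forward")
  }
})

test_that("scaling maps the wedge to the unit band and inverts exactly", {
  th <- runif(50, 0.05, 0.8)
  ol <- omega_low(th)
  oh <- omega_high(th)
  expect_equal(scale_state(th, ol, ol, oh), rep(0, 50))
  expect_equal(scale_state(th, oh, ol, oh), rep(-1, 50))
  sc <- runif(50, -1, 0)
  w <- unscale_state(th, sc, ol, oh)
  expect_lt(max(abs(scale_state(th, w, ol, oh) - sc)), 1e-12)
  expect_lt(max(abs(unscale_state(th, scale_state(th, w, ol, oh), ol, oh) - w)),
            1e-12)
})

test_that("GRF boundary curves have the stated loci", {
  # the end-of-stance locus crosses the wedge only near its right edge
  ths <- seq(0.809, 0.849, by = 0.002)
  gc <- gamma_grf_curves(ths)
  # start-of-stance locus in closed form
  expect_lt(abs(-sqrt(cos(0.3)) - (-0.977413)), 1e-5)
  # end-of-stance locus: states just beyond it fail the end GRF check
  gm <- gc$gamma_grf_minus
  th0 <- gm$samples$theta_plus[3]
  w0 <- gm$samples$thetadot_plus[3]
  pre_in <- integrate_stance(walker_state(th0, w0 + 1e-3))
  pre_out <- integrate_stance(walker_state(th0, w0 - 1e-3))
  m_in <- cos(pre_in$theta_minus) - pre_in$thetadot_minus^2
  m_out <- cos(pre_out$theta_minus) - pre_out$thetadot_minus^2
  expect_true(xor(m_in >= 0, m_out >= 0))
})

test_that("boundary fitting reproduces nodes and preserves shape", {
  x <- seq(0.1, 0.8, length.out = 12)
  y <- -sqrt(x)   # monotone samples
  bc <- fit_boundary(data.frame(theta_plus = x, thetadot_plus = y),
                     kind = "shape_preserving_cubic")
  expect_lt(max(abs(bc$fun(x) - y)), 1e-14)
  xf <- seq(0.1, 0.8, length.out = 500)
  expect_true(all(diff(bc$fun(xf)) < 1e-12))   # no overshoot between nodes
  bc2 <- fit_boundary(data.frame(theta_plus = x, thetadot_plus = y),
                      kind = "curvature_continuous_cubic")
  expect_lt(max(abs(bc2$fun(x) - y)), 1e-14)
  expect_error(fit_boundary(data.frame(theta_plus = rev(x), thetadot_plus = y)),
               "ordered")
})

test_that("composite Simpson quadrature is exact for cubics", {
  x <- seq(0, 1, length.out = 51)
  expect_equal(simpson_integral(rep(2, 51), x[2]), 2, tolerance = 1e-14)
  expect_equal(simpson_integral(x^3 - 2 * x^2 + x, x[2]),
               1 / 4 - 2 / 3 + 1 / 2, tolerance = 1e-12)
  # even sample count handled via the 3/8 completion, still cubic-exact
  x2 <- seq(0, 1, length.out = 50)
  expect_equal(simpson_integral(x2^3, x2[2]), 1 / 4, tolerance = 1e-12)
})

test_that("region areas integrate the column bands in original units", {
  g <- grid_spec(60, 41, 0.6)
  omlow <- rep(0, g$n_theta)      # synthetic wedge of unit scaled height
  omhigh <- rep(-0.5, g$n_theta)  # original height 0.5 everywhere
  mask <- matrix(FALSE, g$n_sc, g$n_theta)
  mask[11:31, ] <- TRUE           # band sc in [-0.25, -0.75]
  a <- region_area(mask, g, omlow, omhigh)
  # extent: sc band height 0.5 + two half-cell midpoints -> 0.5 + dsc
  expect_equal(a, (0.5 + g$dsc) * 0.5 * (0.6 - g$dtheta),
               tolerance = 1e-10)
  # an analytically known region: membership under a cubic boundary
  up <- -0.1 - 0.2 * g$theta^2
  mask2 <- sapply(seq_len(g$n_theta), function(j) g$sc <= up[j] / 0.5)
  a2 <- region_area(mask2, g, omlow, omhigh)
  exact <- simpson_integral(0.5 + up, g$dtheta)  # band from the cubic to the floor
  expect_lt(abs(a2 - exact), 0.02 * abs(exact))
})
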