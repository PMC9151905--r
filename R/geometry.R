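#' Slow heel-strike boundary of the 1-step wedge
#'
#' Below this rate (in magnitude) the stance leg never passes vertical: the
#' stance pendulum integral `thetadot^2/2 + cos(theta)` must exceed 1, so the
#' critical rate is `-sqrt(2 (1 - cos(theta)))`.
#'
#' @param theta_plus stance angle(s) in `(0, theta_cap]`.
#' @return Critical post-heel-strike rate(s) (non-positive).
#' @export
omega_low <- function(theta_plus) {
  stopifnot(all(theta_plus >= -1e-8))   # event-tolerance slack at the origin
  -sqrt(2 * (1 - cos(pmax(theta_plus, 0))))
}

#' Fast heel-strike boundary of the 1-step wedge
#'
#' Above this rate (in magnitude) the walker falls forward before any
#' legitimate heel strike. There is no closed form; each value is located by
#' bisection on the stance outcome (legitimate heel strike vs. fall).
#'
#' @param theta_plus stance angle(s) in `(0, theta_cap]`.
#' @param control a [walker_control()].
#' @param tol bisection tolerance on the rate.
#' @return Critical rate(s), more negative than [omega_low()].
#' @export
omega_high <- function(theta_plus, control = walker_control(), tol = 1e-8) {
  vapply(theta_plus, function(th) {
    lo <- omega_low(th)
    hs <- lo - 1e-7            # just inside: passes vertical, heel strike
    cl <- function(w) {
      as.integer(cpp_stance(th, w, control$reltol, control$abstol,
                            control$tcap, control$fall_angle)[["code"]])
    }
    if (cl(hs) != 0L) {
      # wedge degenerately thin; walk down a little
      hs <- lo - 1e-5
      if (cl(hs) != 0L) stop("no heel-strike bracket found at theta = ", th)
    }
    # expand downward to find a falling rate
    off <- 0.02
    repeat {
      fa <- lo - off
      if (cl(fa) != 0L) break
      hs <- fa
      off <- off * 2
      if (off > 4) stop("no fall bracket found at theta = ", th)
    }
    while (hs - fa > tol) {
      mid <- 0.5 * (hs + fa)
      if (cl(mid) == 0L) hs <- mid else fa <- mid
    }
    0.5 * (hs + fa)
  }, numeric(1))
}

#' Scale / unscale the wedge to the unit band
#'
#' In scaled coordinates the rate is measured as a fraction of the local wedge
#' height: `sc = (thetadot - omega_low) / (omega_low - omega_high)`, so the
#' slow boundary maps to 0 and the fast boundary to -1 at every stance angle.
#'
#' @param theta_plus stance angle(s).
#' @param thetadot_plus rate(s) in original units (for [scale_state()]) .
#' @param thetadot_scaled scaled rate(s) (for [unscale_state()]).
#' @param omlow,omhigh optional precomputed boundary values at `theta_plus`
#'   (vectors); supplied by grid code to avoid repeated bisection.
#' @param control a [walker_control()].
#' @return The scaled (resp. original) rate(s).
#' @export
scale_state <- function(theta_plus, thetadot_plus, omlow = NULL, omhigh = NULL,
                        control = walker_control()) {
  if (is.null(omlow)) omlow <- omega_low(theta_plus)
  if (is.null(omhigh)) omhigh <- omega_high(theta_plus, control)
  h <- omlow - omhigh
  stopifnot(all(h > 0))
  (thetadot_plus - omlow) / h
}

#' @rdname scale_state
#' @export
unscale_state <- function(theta_plus, thetadot_scaled, omlow = NULL,
                          omhigh = NULL, control = walker_control()) {
  if (is.null(omlow)) omlow <- omega_low(theta_plus)
  if (is.null(omhigh)) omhigh <- omega_high(theta_plus, control)
  omlow + thetadot_scaled * (omlow - omhigh)
}

#' Ground-reaction-force boundary curves
#'
#' The start-of-stance condition `cos(theta+) = (thetadot+)^2` defines the
#' curve `Gamma_GRF+` in closed form; the end-of-stance condition
#' `cos(theta-) = (thetadot-)^2`, pulled back through the stance flow to the
#' initial state, defines `Gamma_GRF-`, found per stance-angle column by root
#' finding on the simulated pre-impact state.
#'
#' @param theta_plus stance angles at which to sample the curves.
#' @param control a [walker_control()].
#' @param tol root-finding tolerance on the rate.
#' @return A list with elements `gamma_grf_plus` and `gamma_grf_minus`, each a
#'   [fit_boundary()] curve (samples may contain `NA` where the locus does not
#'   cross the wedge at that column; such columns are dropped from the fit).
#' @export
gamma_grf_curves <- function(theta_plus, control = walker_control(),
                             tol = 1e-9) {
  gp <- -sqrt(cos(theta_plus))
  omlow <- omega_low(theta_plus)
  omhigh <- omega_high(theta_plus, control)
  end_margin <- function(th, w) {
    r <- cpp_stance(th, w, control$reltol, control$abstol, control$tcap,
                    control$fall_angle)
    if (as.integer(r[["code"]]) != 0L) return(NA_real_)
    cos(r[["theta_minus"]]) - r[["thetadot_minus"]]^2
  }
  gm <- vapply(seq_along(theta_plus), function(i) {
    th <- theta_plus[i]
    h <- omlow[i] - omhigh[i]
    # the locus can be a band interior to the wedge: scan from the slow side
    # and refine the first sign change
    ws <- omlow[i] - h * seq(1e-4, 1 - 1e-4, length.out = 40)
    ms <- vapply(ws, function(w) end_margin(th, w), numeric(1))
    ok <- which(!is.na(ms))
    s <- ok[which(diff(sign(ms[ok])) != 0)]
    if (!length(s)) return(NA_real_)
    k <- s[1]
    k2 <- ok[match(k, ok) + 1]
    uniroot(function(w) end_margin(th, w), sort(c(ws[k], ws[k2])),
            tol = tol)$root
  }, numeric(1))
  keep_p <- gp <= omlow & gp >= omhigh     # only where the locus is in the wedge
  list(
    gamma_grf_plus = fit_boundary(
      data.frame(theta_plus = theta_plus, thetadot_plus = ifelse(keep_p, gp, NA)),
      kind = "curvature_continuous_cubic", name = "Gamma_GRF_plus"),
    gamma_grf_minus = fit_boundary(
      data.frame(theta_plus = theta_plus, thetadot_plus = gm),
      kind = "curvature_continuous_cubic", name = "Gamma_GRF_minus"))
}

#' Fit a boundary curve through ordered samples
#'
#' Smooth analytic boundaries use curvature-continuous cubic spline
#' interpolation; grid-estimated boundaries use monotone shape-preserving
#' piecewise cubics (Fritsch-Carlson) which cannot overshoot, as appropriate
#' for envelopes fitted through grid points.
#'
#' @param samples data frame with columns `theta_plus` and `thetadot_plus`
#'   (rows with `NA` are dropped), strictly increasing in `theta_plus`.
#' @param kind `"curvature_continuous_cubic"` or `"shape_preserving_cubic"`.
#' @param name optional curve name.
#' @return An object of class `boundary_curve`: a list with the cleaned
#'   `samples`, the `kind`, the `name`, and `fun(theta)` which evaluates the
#'   interpolant (constant extrapolation beyond the sample hull).
#' @export
fit_boundary <- function(samples,
                         kind = c("curvature_continuous_cubic",
                                  "shape_preserving_cubic"),
                         name = NULL) {
  kind <- match.arg(kind)
  samples <- samples[stats::complete.cases(samples[, c("theta_plus", "thetadot_plus")]), ]
  if (nrow(samples) < 4) stop("need at least 4 non-missing samples")
  if (any(diff(samples$theta_plus) <= 0))
    stop("samples must be strictly ordered in theta_plus")
  method <- if (kind == "curvature_continuous_cubic") "fmm" else "monoH.FC"
  f <- splinefun(samples$theta_plus, samples$thetadot_plus, method = method)
  rng <- range(samples$theta_plus)
  structure(list(samples = samples, kind = kind, name = name,
                 range = rng,
                 fun = function(theta) f(pmin(pmax(theta, rng[1]), rng[2]))),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve> %s (%s), %d samples on [%.4g, %.4g]\n",
              x$name %||% "?", x$kind, nrow(x$samples), x$range[1], x$range[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Composite Simpson quadrature on uniform samples
#'
#' Integrates sampled values on a uniform abscissa by the composite Simpson
#' rule; an even panel count is completed with a Simpson 3/8 rule on the last
#' four points so cubic exactness is retained.
#'
#' @param y sampled integrand values.
#' @param dx uniform spacing.
#' @return The integral estimate.
#' @export
simpson_integral <- function(y, dx) {
  n <- length(y)
  stopifnot(n >= 3, dx > 0)
  if (n %% 2 == 1) {
    w <- c(1, rep(c(4, 2), length.out = n - 2), 1)
    w[n - 1] <- 4
    return(dx / 3 * sum(w * y))
  }
  # even number of samples: Simpson on 1..n-3, 3/8 on the last four
  if (n == 4) return(dx * 3 / 8 * sum(c(1, 3, 3, 1) * y))
  head_part <- simpson_integral(y[1:(n - 3)], dx)
  head_part + dx * 3 / 8 * sum(c(1, 3, 3, 1) * y[(n - 3):n])
}

#' Uniform analysis grid over the scaled state space
#'
#' Columns are stance angles `theta = j * theta_max / n_theta`
#' (`j = 1..n_theta`); rows are scaled rates from 0 down to -1. The
#' reference resolution used for the headline area figures is 42500 x 1002;
#' the default here is a desk-scale 850 x 201 grid.
#'
#' @param n_theta,n_sc number of columns / rows.
#' @param theta_max largest stance angle (the analysis cap).
#' @return A list of class `grid_spec` with `theta` (columns), `sc` (rows),
#'   `dtheta`, `dsc`.
#' @export
grid_spec <- function(n_theta = 850, n_sc = 201, theta_max = 0.85) {
  stopifnot(n_theta >= 10, n_sc >= 11)
  dtheta <- theta_max / n_theta
  structure(list(n_theta = as.integer(n_theta), n_sc = as.integer(n_sc),
                 theta_max = theta_max, dtheta = dtheta,
                 theta = seq_len(n_theta) * dtheta,
                 sc = seq(0, -1, length.out = n_sc),
                 dsc = 1 / (n_sc - 1)),
            class = "grid_spec")
}

# ---- column-band machinery -------------------------------------------------

# contiguous TRUE runs of a logical vector: matrix with columns from,to
true_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(from = starts[r$values], to = ends[r$values])
}

# per-column total band height in scaled units, half-cell midpoint edges
column_band_heights <- function(mask, grid) {
  dsc <- grid$dsc
  vapply(seq_len(ncol(mask)), function(j) {
    runs <- true_runs(mask[, j])
    if (nrow(runs) == 0) return(0)
    h <- 0
    for (k in seq_len(nrow(runs))) {
      top <- grid$sc[runs[k, 1]] + if (runs[k, 1] > 1L) dsc / 2 else 0
      bot <- grid$sc[runs[k, 2]] - if (runs[k, 2] < grid$n_sc) dsc / 2 else 0
      h <- h + (top - bot)
    }
    h
  }, numeric(1))
}

#' Area of a gridded region in original state-space coordinates
#'
#' Converts per-column band extents from scaled to original rate units by the
#' local wedge height and integrates across stance angle with the composite
#' Simpson rule. Band edges are placed midway between the outermost member
#' grid point and the adjacent non-member (half-cell convention); multiple
#' disjoint bands per column are summed.
#'
#' @param region a `region_estimate` (see [one_step_viable_region()]), or a
#'   logical membership matrix together with `grid`, `omlow`, `omhigh`.
#' @param grid,omlow,omhigh used when `region` is a bare matrix.
#' @return Area in original `(theta, thetadot)` units.
#' @export
region_area <- function(region, grid = NULL, omlow = NULL, omhigh = NULL) {
  if (inherits(region, "region_estimate")) {
    grid <- region$grid; omlow <- region$omlow; omhigh <- region$omhigh
    mask <- region$membership
  } else mask <- region
  stopifnot(is.matrix(mask), nrow(mask) == grid$n_sc, ncol(mask) == grid$n_theta)
  hsc <- column_band_heights(mask, grid)
  simpson_integral(hsc * (omlow - omhigh), grid$dtheta)
}

new_region_estimate <- function(grid, membership, omlow, omhigh,
                                boundaries = NULL, name = NULL) {
  r <- structure(list(grid = grid, membership = membership, omlow = omlow,
                      omhigh = omhigh, boundaries = boundaries, name = name,
                      area = NA_real_),
                 class = "region_estimate")
  r$area <- region_area(r)
  r
}

#' @export
print.region_estimate <- function(x, ...) {
  cat(sprintf("<region_estimate> %s: %d x %d grid, %d member points, area %.6g\n",
              x$name %||% "?", x$grid$n_sc, x$grid$n_theta,
              sum(x$membership), x$area))
  invisible(x)
}
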