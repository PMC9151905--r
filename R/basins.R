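#' Step-to-step controllers for basin estimation
#'
#' `open_loop(P_star)` applies a constant push-off every step (infeasible
#' push-offs are viability violations); `speed_regulated(V_star)` applies the
#' one-step-optimal clipped push-off toward a target speed.
#'
#' @param P_star constant push-off impulse.
#' @param V_star target step speed.
#' @return A controller description of class `walker_controller`.
#' @export
open_loop <- function(P_star) {
  stopifnot(P_star >= 0)
  structure(list(mode = 0L, param = P_star, label = sprintf("open_loop(P*=%g)", P_star)),
            class = "walker_controller")
}

#' @rdname open_loop
#' @export
speed_regulated <- function(V_star) {
  stopifnot(V_star > 0)
  structure(list(mode = 1L, param = V_star,
                 label = sprintf("speed_regulated(V*=%g)", V_star)),
            class = "walker_controller")
}

# strided subgrid of a kernel grid; stride must divide the column count and
# the row-interval count so the subgrid is itself uniform with aligned ends
subgrid_of <- function(grid, stride) {
  s_th <- stride[1]; s_sc <- stride[2]
  if (grid$n_theta %% s_th != 0 || (grid$n_sc - 1) %% s_sc != 0)
    stop("stride must divide the grid: n_theta %% stride_theta == 0 and (n_sc - 1) %% stride_sc == 0")
  cols <- seq(s_th, grid$n_theta, by = s_th)
  rows <- seq(1L, grid$n_sc, by = s_sc)
  g <- grid_spec(length(cols), length(rows), grid$theta_max)
  list(grid = g, rows = rows, cols = cols)
}

# scaled coordinate of a state, using the kernel's fast-boundary spline
kernel_scale <- function(kernel, theta, thetadot) {
  ol <- omega_low(theta)
  oh <- splinefun(kernel$grid$theta, kernel$omhigh, method = "fmm")(
    pmin(pmax(theta, kernel$grid$theta[1]), kernel$grid$theta_max))
  (thetadot - ol) / (ol - oh)
}

#' Estimate a basin of attraction on the kernel grid
#'
#' Simulates the controlled walker from every kernel grid point (optionally
#' strided for speed) for `n_steps` steps; membership requires that no
#' viability constraint is violated at any step and that the terminal state
#' lies within `term_tol` of the attractor in scaled coordinates. The speed
#' regulator inside the sweep optimises over an interpolated speed table
#' built from the kernel's cached stance results (one stance integration per
#' realised step); single-step calls outside sweeps use the direct optimiser,
#' and the two agree to interpolation accuracy.
#'
#' @param kernel a [viability_kernel()].
#' @param controller an [open_loop()] or [speed_regulated()] controller.
#' @param gait the attractor gait ([find_fixed_point()] result).
#' @param n_steps steps per start (default 50 open-loop, 25 regulated).
#' @param stride `c(theta_stride, rate_stride)` subsampling of start points.
#' @param term_tol terminal convergence tolerance (scaled coordinates).
#' @param early_tol early-exit tolerance (trajectory declared converged).
#' @param control a [walker_control()] (defaults to the kernel's).
#' @param optimizer `"global"` (default): the regulator minimises the cost
#'   over all admissible push-offs; `"anchored"`: exploratory variant that
#'   restricts the search to the feasible push-off run containing the
#'   previously applied value.
#' @return An object of class `basin_estimate`: membership matrix on the
#'   subgrid, the matching kernel submask, `area_fraction_of_kernel`
#'   (percent), the controller, gait, and bookkeeping fields.
#' @export
estimate_basin <- function(kernel, controller, gait, n_steps = NULL,
                           stride = c(1L, 1L), term_tol = 1e-2,
                           early_tol = 1e-6, control = NULL,
                           optimizer = c("global", "anchored")) {
  optimizer <- match.arg(optimizer)
  stopifnot(inherits(kernel, "viability_kernel"),
            inherits(controller, "walker_controller"),
            inherits(gait, "gait_fixed_point"))
  if (is.null(control)) control <- kernel$control
  if (is.null(n_steps)) n_steps <- if (controller$mode == 0L) 50L else 25L
  sg <- subgrid_of(kernel$grid, stride)
  kmask <- kernel$membership[sg$rows, sg$cols, drop = FALSE]
  omlow_s <- kernel$omlow[sg$cols]
  omhigh_s <- kernel$omhigh[sg$cols]
  idx <- which(kmask)
  ii <- (idx - 1L) %% sg$grid$n_sc + 1L
  jj <- (idx - 1L) %/% sg$grid$n_sc + 1L
  th <- sg$grid$theta[jj]
  w <- omlow_s[jj] + sg$grid$sc[ii] * (omlow_s[jj] - omhigh_s[jj])
  attr_sc <- kernel_scale(kernel, gait$state[[1]], gait$state[[2]])
  res <- cpp_basin(cbind(th, w), controller$mode, controller$param,
                   as.integer(n_steps), kernel$grid$dtheta,
                   kernel$grid$dtheta, kernel$omlow, kernel$omhigh,
                   kernel$speed, gait$state[[1]], attr_sc, term_tol,
                   early_tol, control$pushoff_cap, control$reltol,
                   control$abstol, control$tcap, control$fall_angle,
                   kernel$grid$theta_max,
                   if (optimizer == "anchored") 1L else 0L, gait$pushoff)
  member <- matrix(FALSE, sg$grid$n_sc, sg$grid$n_theta)
  member[idx] <- res[, "member"] > 0
  kernel_area <- region_area(kmask, sg$grid, omlow_s, omhigh_s)
  basin_area <- region_area(member, sg$grid, omlow_s, omhigh_s)
  structure(list(controller = controller, gait = gait,
                 membership = member, kernel_mask = kmask,
                 grid = sg$grid, rows = sg$rows, cols = sg$cols,
                 omlow = omlow_s, omhigh = omhigh_s,
                 n_steps = n_steps, term_tol = term_tol,
                 area = basin_area, kernel_area = kernel_area,
                 area_fraction_of_kernel = 100 * basin_area / kernel_area,
                 fail_codes = table(failure_label(res[, "code"]))),
            class = "basin_estimate")
}

#' @export
print.basin_estimate <- function(x, ...) {
  cat(sprintf("<basin_estimate> %s: %.2f%% of kernel (%d member points, %d steps)\n",
              x$controller$label, x$area_fraction_of_kernel,
              sum(x$membership), x$n_steps))
  invisible(x)
}

#' Coverage of the kernel by a collection of basins
#'
#' @param basins list of [estimate_basin()] results on the same subgrid.
#' @return A list of class `coverage_report`: `union_fraction` (percent of
#'   kernel area), `fractions` per basin, `pairwise_overlaps` (percent,
#'   matrix), and `adjacent_overlaps_positive`.
#' @export
coverage <- function(basins) {
  stopifnot(length(basins) >= 1)
  g0 <- basins[[1]]$grid
  for (b in basins)
    if (!identical(dim(b$membership), dim(basins[[1]]$membership)))
      stop("basins are on different grids")
  un <- Reduce(`|`, lapply(basins, function(b) b$membership))
  ka <- basins[[1]]$kernel_area
  un_area <- region_area(un, g0, basins[[1]]$omlow, basins[[1]]$omhigh)
  n <- length(basins)
  ov <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    inter <- basins[[i]]$membership & basins[[j]]$membership
    ov[i, j] <- 100 * region_area(inter, g0, basins[[1]]$omlow,
                                  basins[[1]]$omhigh) / ka
  }
  labels <- vapply(basins, function(b) b$controller$label, character(1))
  dimnames(ov) <- list(labels, labels)
  adj <- if (n > 1) all(diag(ov[-1, -n, drop = FALSE]) > 0) else NA
  structure(list(union_fraction = 100 * un_area / ka,
                 fractions = vapply(basins, function(b)
                   b$area_fraction_of_kernel, numeric(1)),
                 pairwise_overlaps = ov,
                 adjacent_overlaps_positive = adj,
                 union_membership = un),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> union %.4f%% of kernel; basin fractions: %s\n",
              x$union_fraction,
              paste(sprintf("%.2f", x$fractions), collapse = ", ")))
  invisible(x)
}

#' Level-curve prediction of a speed-regulated basin
#'
#' For sufficiently fast targets the regulated basin is delimited by level
#' curves of the pre-impact angle, `{theta- = constant}`, and by the kernel's
#' own boundaries. The constants are fitted to the simulated basin's edges
#' (the empirical mode), the predicted basin is the kernel slab between the
#' level curves, and the level-curve property itself can be verified by
#' sampling the fitted curves.
#'
#' @param basin a speed-regulated [estimate_basin()] result.
#' @param kernel the matching [viability_kernel()].
#' @param min_speed regime guard: below this target speed the basin structure
#'   is shaped by actuation limits and the prediction is declined.
#' @param trim quantile trim when fitting the level constants.
#' @return A list of class `basin_prediction` with `declined`, the fitted
#'   constants `c_left`, `c_right`, `predicted_fraction` and
#'   `simulated_fraction` (percent of kernel area).
#' @export
predict_regulated_boundaries <- function(basin, kernel, min_speed = 0.1,
                                         trim = 0.002) {
  stopifnot(inherits(basin, "basin_estimate"))
  if (basin$controller$mode != 1L)
    stop("prediction applies to speed-regulated basins")
  if (basin$controller$param < min_speed)
    return(structure(list(declined = TRUE,
                          reason = sprintf(
                            "target speed %.3g below the level-curve regime (actuation limits shape the basin)",
                            basin$controller$param)),
                     class = "basin_prediction"))
  thm <- kernel$theta_minus[basin$rows, basin$cols, drop = FALSE]
  vals <- thm[basin$membership]
  c_left <- quantile(vals, 1 - trim, names = FALSE)   # shallowest pre-impact
  c_right <- quantile(vals, trim, names = FALSE)      # deepest pre-impact
  pred <- basin$kernel_mask & !is.na(thm) & thm <= c_left & thm >= c_right
  pf <- 100 * region_area(pred, basin$grid, basin$omlow, basin$omhigh) /
    basin$kernel_area
  structure(list(declined = FALSE, c_left = c_left, c_right = c_right,
                 predicted_fraction = pf,
                 simulated_fraction = basin$area_fraction_of_kernel,
                 predicted_membership = pred),
            class = "basin_prediction")
}

#' @export
print.basin_prediction <- function(x, ...) {
  if (x$declined) cat("<basin_prediction> declined:", x$reason, "\n")
  else cat(sprintf(
    "<basin_prediction> theta- in [%.5f, %.5f]: predicted %.2f%%, simulated %.2f%%\n",
    x$c_right, x$c_left, x$predicted_fraction, x$simulated_fraction))
  invisible(x)
}

#' Sample a level curve of the pre-impact angle
#'
#' Traces `{theta-(x) = c}` through the wedge by root finding along rate
#' rows, verifying the defining property of the fitted basin boundaries.
#'
#' @param kernel a [viability_kernel()].
#' @param c_level the pre-impact angle constant.
#' @param n number of rate rows to sample.
#' @return Data frame with `theta_plus`, `thetadot_plus`, `theta_minus`
#'   (achieved), `residual`.
#' @export
level_curve <- function(kernel, c_level, n = 21) {
  grid <- kernel$grid
  control <- kernel$control
  rows <- round(seq(2, grid$n_sc - 1, length.out = n))
  out <- list()
  for (i in rows) {
    tm <- kernel$theta_minus[i, ]
    ok <- which(!is.na(tm))
    if (length(ok) < 2) next
    s <- ok[which(diff(sign(tm[ok] - c_level)) != 0)]
    if (!length(s)) next
    j <- s[1]; j2 <- ok[match(j, ok) + 1]
    f <- function(th) {
      ol <- omega_low(th)
      oh <- splinefun(grid$theta, kernel$omhigh, method = "fmm")(th)
      w <- ol + grid$sc[i] * (ol - oh)
      r <- cpp_stance(th, w, control$reltol, control$abstol, control$tcap,
                      control$fall_angle)
      if (as.integer(r[["code"]]) != 0L) return(NA_real_)
      r[["theta_minus"]] - c_level
    }
    r <- tryCatch(uniroot(f, c(grid$theta[j], grid$theta[j2]), tol = 1e-10),
                  error = function(e) NULL)
    if (is.null(r)) next
    th <- r$root
    ol <- omega_low(th)
    oh <- splinefun(grid$theta, kernel$omhigh, method = "fmm")(th)
    out[[length(out) + 1L]] <- data.frame(
      theta_plus = th, thetadot_plus = ol + grid$sc[i] * (ol - oh),
      theta_minus = c_level + f(th), residual = abs(f(th)))
  }
  do.call(rbind, out)
}
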