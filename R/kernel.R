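#' Is a state 1-step viable?
#'
#' A state is 1-step viable when it lies in the wedge between the slow and
#' fast heel-strike boundaries, satisfies the start-of-stance ground-reaction
#' condition, and its simulated pre-impact state satisfies the end-of-stance
#' condition.
#'
#' @inheritParams integrate_stance
#' @return Logical.
#' @export
one_step_viable <- function(state, control = walker_control()) {
  x <- as_walker_state(state)
  if (cos(x[[1]]) - x[[2]]^2 < 0) return(FALSE)
  pre <- integrate_stance(x, control)
  if (is_stance_failure(pre)) return(FALSE)
  cos(pre$theta_minus) - pre$thetadot_minus^2 >= 0
}

#' Grid estimate of the 1-step viable region
#'
#' Classifies every point of a scaled-space grid by one stance integration:
#' membership requires a legitimate heel strike and both ground-reaction
#' endpoint conditions. All stance results are cached per grid point (the
#' pre-impact state, step time, step speed, and the difference-inclusion
#' image), since downstream kernel iteration and basin estimation reuse them.
#'
#' @param grid a [grid_spec()].
#' @param control a [walker_control()].
#' @return An object of class `v1_region` (inherits `region_estimate`) with
#'   the membership matrix and cached tables `theta_minus`, `thetadot_minus`,
#'   `tau`, `speed`, `theta_next`, `w_lo`, `w_hi` (the attainable next-rate
#'   interval endpoints, `-Inf` allowed).
#' @export
one_step_viable_region <- function(grid = grid_spec(),
                                   control = walker_control()) {
  omlow <- omega_low(grid$theta)
  omhigh <- omega_high(grid$theta, control)
  th <- matrix(rep(grid$theta, each = grid$n_sc), nrow = grid$n_sc)
  w <- matrix(rep(omlow, each = grid$n_sc), nrow = grid$n_sc) +
    grid$sc * (matrix(rep(omlow - omhigh, each = grid$n_sc), nrow = grid$n_sc))
  states <- cbind(as.vector(th), as.vector(w))
  B <- cpp_stance_batch(states, control$reltol, control$abstol, control$tcap,
                        control$fall_angle)
  dim_ <- c(grid$n_sc, grid$n_theta)
  code <- matrix(B[, "code"], nrow = grid$n_sc)
  thm <- matrix(B[, "theta_minus"], nrow = grid$n_sc)
  thdm <- matrix(B[, "thetadot_minus"], nrow = grid$n_sc)
  tau <- matrix(B[, "tau"], nrow = grid$n_sc)
  ok <- code == 0
  grf_start <- cos(th) - w^2 >= 0
  grf_end <- ok & (cos(thm) - thdm^2 >= 0)
  member <- ok & grf_start & grf_end
  c2 <- cos(2 * thm)
  shallow <- thm > -pi / 4
  # attainable next-rate interval over admissible push-offs: for shallow
  # pre-impact angles the ends are the P = 0 and P = p_max images; for steep
  # ones p_min already brings the rate to 0 and p_max is unbounded
  w_hi <- ifelse(shallow, thdm * c2, 0)
  w_lo <- ifelse(shallow, thdm / c2, -Inf)
  speed <- ifelse(ok, 2 * sin(-thm) / tau, NA_real_)
  r <- new_region_estimate(grid, member, omlow, omhigh, name = "V1")
  r$theta_minus <- ifelse(ok, thm, NA_real_)
  r$thetadot_minus <- ifelse(ok, thdm, NA_real_)
  r$tau <- ifelse(ok, tau, NA_real_)
  r$speed <- speed
  r$theta_next <- ifelse(ok, -thm, NA_real_)
  r$w_lo <- ifelse(ok, w_lo, NA_real_)
  r$w_hi <- ifelse(ok, w_hi, NA_real_)
  r$stance_code <- code
  r$control <- control
  class(r) <- c("v1_region", class(r))
  r
}

#' Difference-inclusion image of a state
#'
#' Over all admissible push-offs, the reachable set of next-step states is a
#' vertical segment at `theta_next = -theta_minus`: the attainable rate
#' interval is `[thetadot-/cos(2 theta-), thetadot- cos(2 theta-)]` for
#' `-pi/4 < theta- <= 0` and `(-Inf, 0]` for steeper pre-impact angles.
#'
#' @inheritParams integrate_stance
#' @return A list with `theta_next` and `rate_interval` (length-2, lower end
#'   may be `-Inf`).
#' @export
inclusion_image <- function(state, control = walker_control()) {
  pre <- integrate_stance(state, control)
  if (is_stance_failure(pre))
    stop("state is not 1-step viable: stance failed with ", pre$failure)
  thm <- pre$theta_minus; thdm <- pre$thetadot_minus
  if (thm > -pi / 4) {
    iv <- c(thdm / cos(2 * thm), thdm * cos(2 * thm))
  } else {
    iv <- c(-Inf, 0)
  }
  list(theta_next = -thm, rate_interval = iv)
}

# per-column enveloping boundaries of a mask: the sc values of the first
# non-member grid row beyond the (largest) member run, fitted later with
# shape-preserving cubics.  Returns NA for empty columns.
column_envelopes <- function(mask, grid) {
  up <- rep(NA_real_, grid$n_theta)
  lo <- rep(NA_real_, grid$n_theta)
  for (j in seq_len(grid$n_theta)) {
    runs <- true_runs(mask[, j])
    if (nrow(runs) == 0) next
    k <- which.max(runs[, 2] - runs[, 1])
    i1 <- runs[k, 1]; i2 <- runs[k, 2]
    up[j] <- if (i1 > 1L) grid$sc[i1 - 1L] else grid$sc[1] + grid$dsc
    lo[j] <- if (i2 < grid$n_sc) grid$sc[i2 + 1L] else grid$sc[grid$n_sc] - grid$dsc
  }
  list(upper = up, lower = lo)
}

envelope_functions <- function(env, grid) {
  keep <- !is.na(env$upper)
  th <- grid$theta[keep]
  fu <- splinefun(th, env$upper[keep], method = "monoH.FC")
  fl <- splinefun(th, env$lower[keep], method = "monoH.FC")
  rng <- range(th)
  list(upper = function(x) fu(pmin(pmax(x, rng[1]), rng[2])),
       lower = function(x) fl(pmin(pmax(x, rng[1]), rng[2])),
       range = rng)
}

#' Estimate the viability kernel by difference-inclusion iteration
#'
#' Starting from the 1-step viable region, repeatedly removes grid points
#' whose inclusion-image segment fails to intersect the current iterate.
#' Each pass refits shape-preserving boundary envelopes through the
#' non-viable grid points tightly enveloping the current estimate; the
#' segment test is closed-interval overlap against the fitted column
#' interval with half-a-grid-cell tolerance. The inclusion image of every
#' grid point is computed once (cached by [one_step_viable_region()]) since
#' only the membership test changes between passes. Iterates form a nested
#' sequence of j-step viable regions whose limit is the kernel; convergence
#' is a pass with zero removals.
#'
#' @param v1 a `v1_region` from [one_step_viable_region()].
#' @param max_iter iteration guard.
#' @return An object of class `viability_kernel` (inherits `region_estimate`)
#'   with fields `converged_at`, `iterate_areas` (area of every j-step
#'   region), `removals`, envelope boundaries, and the inherited caches.
#' @export
viability_kernel <- function(v1, max_iter = 100) {
  stopifnot(inherits(v1, "v1_region"))
  grid <- v1$grid
  alive <- v1$membership
  idx <- which(alive)
  thn <- v1$theta_next[idx]
  w_hi <- v1$w_hi[idx]
  w_lo <- v1$w_lo[idx]
  # scaled endpoints evaluated at the (off-column) landing angle via the
  # closed-form slow boundary and a spline of the fast boundary
  omh_fun <- splinefun(grid$theta, v1$omhigh, method = "fmm")
  olo_n <- omega_low(thn)
  ohi_n <- omh_fun(pmin(pmax(thn, grid$theta[1]), grid$theta_max))
  hgt_n <- olo_n - ohi_n
  sc_hi <- (w_hi - olo_n) / hgt_n
  sc_lo <- ifelse(is.finite(w_lo), (w_lo - olo_n) / hgt_n, -Inf)
  in_domain <- thn <= grid$theta_max           # leaving the cap = removed
  areas <- v1$area
  removals <- integer(0)
  iter <- 1L
  repeat {
    env <- column_envelopes(alive, grid)
    ef <- envelope_functions(env, grid)
    up_at <- ef$upper(thn) - grid$dsc / 2
    lo_at <- ef$lower(thn) + grid$dsc / 2
    keep <- in_domain & (sc_hi >= lo_at) & (sc_lo <= up_at)
    cur <- alive[idx]
    rem <- cur & !keep
    nrem <- sum(rem)
    removals <- c(removals, nrem)
    if (nrem == 0L) break
    alive[idx[rem]] <- FALSE
    # removed points can no longer serve as landing targets of others only
    # through the refitted envelopes; the per-point images never change
    cur <- alive[idx]
    keepmask <- cur
    idx <- idx[keepmask]; thn <- thn[keepmask]; sc_hi <- sc_hi[keepmask]
    sc_lo <- sc_lo[keepmask]; in_domain <- in_domain[keepmask]
    iter <- iter + 1L
    areas <- c(areas, region_area(alive, grid, v1$omlow, v1$omhigh))
    if (iter > max_iter)
      stop("viability kernel iteration did not converge within ", max_iter,
           " passes; removal history: ", paste(removals, collapse = ", "))
  }
  env <- column_envelopes(alive, grid)
  k <- new_region_estimate(grid, alive, v1$omlow, v1$omhigh, name = "kernel")
  k$converged_at <- iter
  k$iterate_areas <- areas
  k$removals <- removals
  k$envelopes <- env
  k$v1_area <- v1$area
  k$area_ratio <- k$area / v1$area
  # carry caches forward for basins / unreachable-set analysis
  for (f in c("theta_minus", "thetadot_minus", "tau", "speed", "theta_next",
              "w_lo", "w_hi", "stance_code", "control"))
    k[[f]] <- v1[[f]]
  class(k) <- c("viability_kernel", class(k))
  k
}

#' @export
print.viability_kernel <- function(x, ...) {
  cat(sprintf(
    "<viability_kernel> converged at iteration %d; area %.6g (%.4g%% of V1)\n",
    x$converged_at, x$area, 100 * x$area_ratio))
  invisible(x)
}

# label connected components of a logical matrix (8-connectivity)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    lab[start] <- comp
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
        nb <- (jj - 1L) * nr + ii
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- comp
          stack <- c(stack, nb)
        }
      }
    }
  }
  list(labels = lab, n = comp)
}

#' Unreachable subset of the viability kernel
#'
#' Forms, per stance-angle column, the union of the inclusion-image segments
#' of every kernel grid point and returns kernel points not covered by any
#' segment: states the walker's dynamics can never visit, although it can
#' leave them (in one step). Expected to consist of two disjoint components
#' whose inner boundaries are the critical-curve images of the extreme
#' push-offs.
#'
#' @param kernel a [viability_kernel()].
#' @return A list of class `unreachable_set` with the membership matrix,
#'   component labels and count, area, `fraction_of_kernel`, and the
#'   per-column cover used (`gamma1`: upper cover envelope, i.e. the zero
#'   push-off image; `gamma2`: lower cover envelope).
#' @export
unreachable_set <- function(kernel) {
  stopifnot(inherits(kernel, "viability_kernel"))
  grid <- kernel$grid
  alive <- kernel$membership
  idx <- which(alive)
  thn <- kernel$theta_next[idx]
  jn <- round(thn / grid$dtheta)
  keep <- jn >= 1 & jn <= grid$n_theta
  jn <- jn[keep]; idx2 <- idx[keep]
  olo <- kernel$omlow[jn]; ohi <- kernel$omhigh[jn]
  h <- olo - ohi
  sc_hi <- (kernel$w_hi[idx2] - olo) / h
  sc_lo <- ifelse(is.finite(kernel$w_lo[idx2]),
                  (kernel$w_lo[idx2] - olo) / h, -Inf)
  # the covered set per column is the band between the lower and upper
  # envelopes of the image segments binned there (segment intervals vary
  # continuously with the source state, so their union has no interior
  # gaps); columns receiving no image at all are entirely unreachable
  gamma1 <- rep(-Inf, grid$n_theta)  # upper cover envelope (zero-push-off images)
  gamma2 <- rep(Inf, grid$n_theta)   # lower cover envelope
  g1 <- tapply(sc_hi, jn, max)
  g2 <- tapply(sc_lo, jn, min)
  gamma1[as.integer(names(g1))] <- g1
  gamma2[as.integer(names(g2))] <- g2
  scm <- matrix(grid$sc, grid$n_sc, grid$n_theta)
  covered <- scm <= matrix(gamma1, grid$n_sc, grid$n_theta, byrow = TRUE) &
             scm >= matrix(gamma2, grid$n_sc, grid$n_theta, byrow = TRUE)
  unreach <- alive & !covered
  comps <- label_components(unreach)
  sizes <- if (comps$n > 0) tabulate(comps$labels[comps$labels > 0], comps$n)
           else integer(0)
  # major components; single-cell to few-cell flecks are grid noise from the
  # finite sampling of the image set
  major <- sum(sizes >= max(5, 0.01 * sum(unreach)))
  area <- region_area(unreach, grid, kernel$omlow, kernel$omhigh)
  structure(list(membership = unreach, grid = grid,
                 labels = comps$labels, n_components = comps$n,
                 component_sizes = sort(sizes, decreasing = TRUE),
                 n_major_components = major,
                 area = area, fraction_of_kernel = area / kernel$area,
                 gamma1 = gamma1, gamma2 = gamma2),
            class = "unreachable_set")
}

#' @export
print.unreachable_set <- function(x, ...) {
  cat(sprintf(
    "<unreachable_set> %d component(s), area %.4g (%.3g%% of kernel)\n",
    x$n_components, x$area, 100 * x$fraction_of_kernel))
  invisible(x)
}

# find all preimages of target y under the zero-push-off step map, using the
# cached grid images as seeds and Newton refinement
# Trace the level curve {theta_next(x) = y_theta} through the kernel, row by
# row (1-D root finds in the stance angle at fixed scaled rate), recording
# the passive (zero-push-off) landing rate w0 at each curve point.  Preimages
# of (y_theta, y_w) under the P = 0 map are the transversal crossings of
# w0 = y_w along this curve.  Newton iteration is unreliable for this task:
# near the critical curve the map folds and its Jacobian degenerates.
trace_theta_next_level <- function(kernel, y_theta,
                                   control = kernel$control) {
  grid <- kernel$grid
  ohi_fun <- splinefun(grid$theta, kernel$omhigh, method = "fmm")
  image_at <- function(th, sc) {
    ol <- omega_low(th)
    oh <- ohi_fun(pmin(pmax(th, grid$theta[1]), grid$theta_max))
    w <- ol + sc * (ol - oh)
    r <- cpp_stance(th, w, control$reltol, control$abstol, control$tcap,
                    control$fall_angle)
    if (as.integer(r[["code"]]) != 0L) return(c(NA_real_, NA_real_))
    c(-r[["theta_minus"]],
      r[["thetadot_minus"]] * cos(2 * r[["theta_minus"]]))
  }
  pts <- list()
  for (i in seq(2L, grid$n_sc - 1L)) {
    v <- kernel$theta_next[i, ]
    ok <- which(!is.na(v) & kernel$membership[i, ])
    if (length(ok) < 2) next
    dsig <- which(diff(sign(v[ok] - y_theta)) != 0)
    b <- 0L
    for (s in dsig) {
      j1 <- ok[s]; j2 <- ok[s + 1]
      if (j2 != j1 + 1L) next                      # gap in the row: skip
      r <- tryCatch(uniroot(function(th) image_at(th, grid$sc[i])[1] - y_theta,
                            c(grid$theta[j1], grid$theta[j2]), tol = 1e-10),
                    error = function(e) NULL)
      if (is.null(r)) next
      b <- b + 1L
      img <- image_at(r$root, grid$sc[i])
      pts[[length(pts) + 1L]] <- data.frame(row = i, branch = b,
                                            theta = r$root, sc = grid$sc[i],
                                            w0 = img[2])
    }
  }
  if (!length(pts)) return(NULL)
  do.call(rbind, pts)
}

# count the w0 = y_w crossings along a traced level curve
count_level_crossings <- function(df, y_w) {
  if (is.null(df)) return(list())
  sols <- list()
  for (b in unique(df$branch)) {
    d <- df[df$branch == b, ]
    d <- d[order(d$row), ]
    if (nrow(d) < 2) next
    g <- d$w0 - y_w
    for (k in seq_len(nrow(d) - 1)) {
      if (d$row[k + 1] - d$row[k] > 3) next        # broken chain
      if (is.na(g[k]) || is.na(g[k + 1])) next
      if (sign(g[k]) != sign(g[k + 1]) && g[k] != 0) {
        sols[[length(sols) + 1L]] <-
          c(mean(d$theta[k:(k + 1)]), mean(d$sc[k:(k + 1)]))
      }
    }
  }
  sols
}

preimages_p0 <- function(kernel, y_theta, y_sc, control = kernel$control) {
  grid <- kernel$grid
  olo_y <- omega_low(y_theta)
  ohi_fun <- splinefun(grid$theta, kernel$omhigh, method = "fmm")
  y_w <- olo_y + y_sc * (olo_y - ohi_fun(y_theta))
  count_level_crossings(trace_theta_next_level(kernel, y_theta, control), y_w)
}


#' Preimage-count check across the upper unreachable boundary
#'
#' The upper boundary of the unreachable set is the zero-push-off image of
#' the kernel and is expected to belong to a critical curve of the
#' non-invertible step map: the number of preimages of states on opposite
#' sides differs by two. For sampled straddling pairs, counts preimages under
#' the zero-push-off map by multi-start Newton refinement seeded from the
#' cached grid images.
#'
#' @param kernel a [viability_kernel()].
#' @param unreach the matching [unreachable_set()].
#' @param n_pairs number of straddling sample pairs.
#' @param delta straddle offset in scaled units (default 3 grid cells).
#' @return A data frame with columns `theta`, `n_above`, `n_below`, `diff`.
#' @export
critical_curve_check <- function(kernel, unreach, n_pairs = 10,
                                 delta = NULL) {
  grid <- kernel$grid
  if (is.null(delta)) delta <- 3 * grid$dsc
  g1 <- unreach$gamma1
  # restrict to columns where the upper cover boundary is interior to the
  # kernel band (so both sides of the curve are in the kernel)
  env <- column_envelopes(kernel$membership, grid)
  usable <- which(is.finite(g1) & !is.na(env$upper) &
                    g1 < env$upper - 2 * delta & g1 > env$lower + 2 * delta)
  if (length(usable) < n_pairs) n_pairs <- length(usable)
  cols <- usable[round(seq(1, length(usable), length.out = n_pairs))]
  out <- lapply(cols, function(j) {
    th <- grid$theta[j]
    tr <- trace_theta_next_level(kernel, th)
    if (is.null(tr))
      return(data.frame(theta = th, n_above = NA, n_below = NA, diff = NA))
    # the local critical value is the fold of the passive landing rate along
    # the traced level curve (the binned cover envelope carries half-a-column
    # slop, far coarser than the fold's sharpness)
    fold_w <- max(tr$w0, na.rm = TRUE)
    h <- (kernel$omlow - kernel$omhigh)[j]
    dw <- delta * h
    na <- length(count_level_crossings(tr, fold_w + dw))
    nb <- length(count_level_crossings(tr, fold_w - dw))
    data.frame(theta = th, n_above = na, n_below = nb, diff = nb - na)
  })
  do.call(rbind, out)
}

#' Validate the estimated kernel boundaries
#'
#' Checks the dynamical signatures expected of the kernel's boundary pieces:
#' (i) the lower boundary merges smoothly with the fast heel-strike curve at
#' some stance angle (reported); (ii) sampled points of the free lower
#' boundary and of the upper boundary map onto the free lower boundary under
#' zero push-off (within a stated number of grid cells); (iii) sampled
#' boundary points admit an inclusion-image segment intersecting the kernel
#' interior (positive invariance of the closed set).
#'
#' @param kernel a [viability_kernel()].
#' @param n_samples boundary sample count per check.
#' @return A list of class `kernel_boundary_report` with `merge_theta`,
#'   `map_errors_cells` (distance of boundary images from the free lower
#'   boundary, in grid cells), and `invariance_ok` (fraction of sampled
#'   boundary points whose segment meets the kernel).
#' @export
validate_kernel_boundaries <- function(kernel, n_samples = 20) {
  grid <- kernel$grid
  env <- column_envelopes(kernel$membership, grid)
  lower_mid <- env$lower + grid$dsc / 2      # half-cell midpoint convention
  upper_mid <- env$upper - grid$dsc / 2
  nonempty <- which(!is.na(env$lower))
  merged <- !is.na(env$lower) & (lower_mid <= -1 + grid$dsc / 2 + 1e-12)
  # smallest theta at which the lower boundary starts coinciding with
  # Omega_high: the start of the longest contiguous merged stretch (the free
  # part of the lower boundary lies left of it; near the right edge the
  # lower boundary leaves Omega_high again for the ground-reaction curve)
  r <- rle(merged[nonempty])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr <- which(r$values)
  merge_theta <- if (length(tr)) {
    k <- tr[which.max(r$lengths[tr])]
    grid$theta[nonempty[starts[k]]]
  } else NA_real_
  control <- kernel$control
  free <- nonempty[!merged[nonempty]]
  lower_fun <- splinefun(grid$theta[free], lower_mid[free], method = "monoH.FC")
  # (ii) zero-push-off images of Gamma_t and free Gamma_b
  sample_cols <- function(cols, n) cols[unique(round(seq(1, length(cols), length.out = n)))]
  img_err <- function(th, sc) {
    olo <- kernel$omlow[round(th / grid$dtheta)]
    ohi <- kernel$omhigh[round(th / grid$dtheta)]
    w <- olo + sc * (olo - ohi)
    r <- cpp_stance(th, w, control$reltol, control$abstol, control$tcap,
                    control$fall_angle)
    if (as.integer(r[["code"]]) != 0L) return(NA_real_)
    thn <- -r[["theta_minus"]]
    wn <- r[["thetadot_minus"]] * cos(2 * r[["theta_minus"]])
    if (thn < min(grid$theta[free]) || thn > max(grid$theta[free]))
      return(NA_real_)
    olo_n <- omega_low(thn)
    ohi_n <- splinefun(grid$theta, kernel$omhigh, method = "fmm")(thn)
    scn <- (wn - olo_n) / (olo_n - ohi_n)
    abs(scn - lower_fun(thn)) / grid$dsc
  }
  cols_t <- sample_cols(nonempty, n_samples)
  err_t <- vapply(cols_t, function(j) img_err(grid$theta[j], upper_mid[j]),
                  numeric(1))
  cols_b <- sample_cols(free, n_samples)
  err_b <- vapply(cols_b, function(j) img_err(grid$theta[j], lower_mid[j]),
                  numeric(1))
  # (iii) inclusion segments of boundary points intersect the kernel
  ef <- envelope_functions(env, grid)
  seg_ok <- function(th, sc) {
    olo <- omega_low(th)
    ohi <- splinefun(grid$theta, kernel$omhigh, method = "fmm")(th)
    w <- olo + sc * (olo - ohi)
    r <- cpp_stance(th, w, control$reltol, control$abstol, control$tcap,
                    control$fall_angle)
    if (as.integer(r[["code"]]) != 0L) return(FALSE)
    thm <- r[["theta_minus"]]; thdm <- r[["thetadot_minus"]]
    thn <- -thm
    if (thn > grid$theta_max) return(FALSE)
    w_hi <- if (thm > -pi / 4) thdm * cos(2 * thm) else 0
    w_lo <- if (thm > -pi / 4) thdm / cos(2 * thm) else -Inf
    olo_n <- omega_low(thn)
    ohi_n <- splinefun(grid$theta, kernel$omhigh, method = "fmm")(thn)
    h <- olo_n - ohi_n
    sc_hi <- (w_hi - olo_n) / h
    sc_lo <- if (is.finite(w_lo)) (w_lo - olo_n) / h else -Inf
    # boundary points may map onto the boundary itself (closed-set positive
    # invariance), so the test is generous by one grid cell outward
    sc_hi >= ef$lower(thn) - grid$dsc && sc_lo <= ef$upper(thn) + grid$dsc
  }
  # invariance is probed at the outermost member rows (states certainly in
  # the closed kernel estimate; the half-cell midpoints may already lie on
  # the nonviable side)
  all_cols <- sample_cols(nonempty, n_samples)
  inv_up <- vapply(all_cols, function(j)
    seg_ok(grid$theta[j], env$upper[j] - grid$dsc), logical(1))
  inv_lo <- vapply(all_cols, function(j)
    seg_ok(grid$theta[j], env$lower[j] + grid$dsc), logical(1))
  structure(list(merge_theta = merge_theta,
                 gamma_t_image_err_cells = err_t,
                 gamma_b_image_err_cells = err_b,
                 invariance_ok = mean(c(inv_up, inv_lo), na.rm = TRUE)),
            class = "kernel_boundary_report")
}

#' @export
print.kernel_boundary_report <- function(x, ...) {
  cat(sprintf("<kernel_boundary_report> merge at theta+ ~ %.5f\n", x$merge_theta))
  cat(sprintf("  Gamma_t -> Gamma_b image error (cells): median %.2f\n",
              median(x$gamma_t_image_err_cells, na.rm = TRUE)))
  cat(sprintf("  Gamma_b -> Gamma_b image error (cells): median %.2f\n",
              median(x$gamma_b_image_err_cells, na.rm = TRUE)))
  cat(sprintf("  boundary positive-invariance fraction: %.3f\n",
              x$invariance_ok))
  invisible(x)
}
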