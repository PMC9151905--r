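#' Find a period-1 gait (fixed point of the step map)
#'
#' Solves `F(x; P) = x` by damped Newton iteration with a central
#' finite-difference Jacobian. The walker admits two period-1 families at
#' every admissible push-off -- the long- and short-period gaits,
#' distinguished by step duration -- so the returned gait depends on the
#' starting guess.
#'
#' @param P push-off impulse held fixed over steps.
#' @param guess starting state (`c(theta, thetadot)`).
#' @param control a [walker_control()].
#' @param tol residual tolerance (max norm).
#' @param max_iter Newton iteration cap.
#' @param fd_step finite-difference step for the Jacobian.
#' @return An object of class `gait_fixed_point`: `state`, `pushoff`,
#'   `step_time`, `steady_speed`, `eigenvalues` (of the linearised step map),
#'   `residual`.
#' @export
find_fixed_point <- function(P, guess, control = walker_control(),
                             tol = 1e-10, max_iter = 50, fd_step = 1e-6) {
  # raw map (actuation limits not enforced along Newton iterates; feasibility
  # of the solution itself is checked below)
  Fmap <- function(x) {
    r <- cpp_step(x[1], x[2], P, control$reltol, control$abstol, control$tcap,
                  control$fall_angle, FALSE)
    if (as.integer(r[["code"]]) != 0L) return(NULL)
    c(r[["theta_next"]], r[["thetadot_next"]])
  }
  x <- as.numeric(guess)
  res <- NULL
  best <- Inf
  stalled <- 0L
  for (it in seq_len(max_iter)) {
    Fx <- Fmap(x)
    if (is.null(Fx)) stop("step map failed at iterate (", x[1], ", ", x[2], ")")
    res <- Fx - x
    rn <- max(abs(res))
    if (rn < tol) break
    # the residual floor is set by the stance integrator's tolerance; accept
    # a stalled iterate within an order of magnitude of tol
    if (rn >= best * 0.5) stalled <- stalled + 1L else stalled <- 0L
    best <- min(best, rn)
    if (stalled >= 3L && rn < 10 * tol) break
    J <- matrix(NA_real_, 2, 2)
    for (v in 1:2) {
      e <- c(0, 0); e[v] <- fd_step
      fp <- Fmap(x + e); fm <- Fmap(x - e)
      if (is.null(fp) || is.null(fm))
        stop("step map failed while forming the Jacobian")
      J[, v] <- (fp - fm) / (2 * fd_step)
    }
    dx <- solve(J - diag(2), res)
    lambda <- 1
    repeat {
      xn <- x - lambda * dx
      Fn <- Fmap(xn)
      if (!is.null(Fn) && max(abs(Fn - xn)) < max(abs(res)) || lambda < 1e-3)
        break
      lambda <- lambda / 2
    }
    x <- xn
    if (it == max_iter)
      stop("fixed-point iteration did not converge; residual ", max(abs(res)))
  }
  # eigenvalues of the step-map Jacobian at the solution
  J <- matrix(NA_real_, 2, 2)
  for (v in 1:2) {
    e <- c(0, 0); e[v] <- fd_step
    J[, v] <- (Fmap(x + e) - Fmap(x - e)) / (2 * fd_step)
  }
  st <- cpp_step(x[1], x[2], P, control$reltol, control$abstol, control$tcap,
                 control$fall_angle, FALSE)
  lim <- cpp_pushoff_limits(st[["theta_minus"]], st[["thetadot_minus"]])
  structure(list(state = walker_state(x[1], x[2]), pushoff = P,
                 step_time = st[["tau"]], steady_speed = st[["step_speed"]],
                 eigenvalues = eigen(J, only.values = TRUE)$values,
                 jacobian = J, residual = max(abs(res)),
                 pushoff_feasible = P >= lim[["p_min"]] - 1e-12 &&
                   P <= lim[["p_max"]] + 1e-12),
            class = "gait_fixed_point")
}

#' @export
print.gait_fixed_point <- function(x, ...) {
  cat(sprintf(
    "<gait_fixed_point> P* = %.6g: (%.6g, %.6g), tau = %.5g, V* = %.6g\n",
    x$pushoff, x$state[[1]], x$state[[2]], x$step_time, x$steady_speed))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' Locate both period-1 gaits at a given push-off
#'
#' Multi-start Newton search over a coarse sample of the wedge; the two
#' distinct solutions are labelled long- and short-period by step time.
#'
#' @inheritParams find_fixed_point
#' @return Named list with elements `long` and `short`
#'   ([find_fixed_point()] results).
#' @export
seed_fixed_points <- function(P, control = walker_control()) {
  ths <- seq(0.05, 0.45, by = 0.05)
  fps <- list()
  for (th in ths) {
    ol <- omega_low(th); oh <- omega_high(th, control)
    for (f in c(0.25, 0.5, 0.75)) {
      g <- c(th, ol - f * (ol - oh))
      fp <- tryCatch(find_fixed_point(P, g, control),
                     error = function(e) NULL)
      if (is.null(fp) || fp$state[[1]] < 1e-4) next
      dup <- any(vapply(fps, function(o)
        max(abs(unclass(o$state) - unclass(fp$state))) < 1e-7, logical(1)))
      if (!dup) fps[[length(fps) + 1L]] <- fp
      if (length(fps) >= 2) break
    }
    if (length(fps) >= 2) break
  }
  if (length(fps) < 2)
    stop("expected two period-1 gaits at P = ", P, "; found ", length(fps))
  taus <- vapply(fps, function(o) o$step_time, numeric(1))
  list(long = fps[[which.max(taus)]], short = fps[[which.min(taus)]])
}

#' Continue a period-1 gait family in the push-off parameter
#'
#' Natural-parameter continuation with a secant predictor; at every point the
#' eigenvalues of the finite-difference Jacobian are recorded, and
#' bifurcations are located by bisection on the eigenvalue crossing
#' condition: a real eigenvalue through -1 marks a period doubling, through
#' +1 the transcritical exchange where the two families cross.
#'
#' @param branch `"long"` or `"short"`.
#' @param P_range continuation range (increasing).
#' @param step parameter step.
#' @param control a [walker_control()].
#' @param seed optional `gait_fixed_point` to start from (default: seeded at
#'   `P_range[1]`).
#' @return An object of class `gait_branch`: a data frame `points` with
#'   columns `P`, `theta`, `thetadot`, `tau`, `speed`, `eig1`, `eig2`
#'   (real parts; imaginary magnitude in `eig_im`), plus `bifurcations`, a
#'   data frame with `kind` and `P` (and `speed` at the crossing).
#' @export
continue_branch <- function(branch = c("long", "short"),
                            P_range = c(5e-4, 0.85), step = 1e-3,
                            control = walker_control(), seed = NULL) {
  branch <- match.arg(branch)
  P_seed <- min(max(0.05, P_range[1]), P_range[2])
  if (is.null(seed)) seed <- seed_fixed_points(P_seed, control)[[branch]]
  sweep <- function(Ps, fp) {
    out <- matrix(NA_real_, length(Ps), 8,
                  dimnames = list(NULL, c("P", "theta", "thetadot", "tau",
                                          "speed", "eig1", "eig2", "eig_im")))
    prev <- NULL
    for (i in seq_along(Ps)) {
      guess <- unclass(fp$state)
      if (!is.null(prev)) guess <- guess + (guess - prev)   # secant predictor
      prev <- unclass(fp$state)
      fp2 <- tryCatch(find_fixed_point(Ps[i], guess, control),
                      error = function(e) NULL)
      if (is.null(fp2))
        fp2 <- tryCatch(find_fixed_point(Ps[i], unclass(fp$state), control),
                        error = function(e) NULL)
      if (is.null(fp2)) break
      if (fp2$state[[1]] < 1e-5) break        # family collapses at the origin
      fp <- fp2
      ev <- fp$eigenvalues
      out[i, ] <- c(Ps[i], fp$state[[1]], fp$state[[2]], fp$step_time,
                    fp$steady_speed, Re(ev)[order(Re(ev))], max(abs(Im(ev))))
    }
    out[!is.na(out[, 1]), , drop = FALSE]
  }
  # continue outward from the seed in both directions; the downward sweep
  # refines its step near P = 0 where the families collapse to the origin
  up <- sweep(seq(seed$pushoff, P_range[2], by = step), seed)
  dn_Ps <- seq(seed$pushoff - step, max(4e-3, P_range[1]), by = -step)
  if (P_range[1] < 4e-3) {
    fine <- min(step, 2.5e-4)
    dn_Ps <- c(dn_Ps, seq(max(4e-3, P_range[1]) - fine, P_range[1], by = -fine))
  }
  dn <- if (length(dn_Ps)) sweep(dn_Ps, seed) else matrix(numeric(0), 0, 8)
  pts <- as.data.frame(rbind(dn[rev(seq_len(nrow(dn))), , drop = FALSE], up))
  bif <- locate_bifurcations(pts, control)
  structure(list(branch = branch, points = pts, bifurcations = bif,
                 control = control),
            class = "gait_branch")
}

# bisection refinement of eigenvalue crossings along a continued branch
locate_bifurcations <- function(pts, control, tol = 1e-6) {
  res <- list()
  eig_at <- function(P, guess) {
    fp <- find_fixed_point(P, guess, control)
    list(fp = fp, re = sort(Re(fp$eigenvalues)), im = max(abs(Im(fp$eigenvalues))))
  }
  refine <- function(i, which_eig, target, kind) {
    a <- pts$P[i]; b <- pts$P[i + 1]
    ga <- c(pts$theta[i], pts$thetadot[i])
    fa <- (if (which_eig == 1) pts$eig1[i] else pts$eig2[i]) - target
    guess <- ga
    while (b - a > tol) {
      m <- (a + b) / 2
      em <- eig_at(m, guess)
      guess <- unclass(em$fp$state)
      fm <- em$re[which_eig] - target
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    em <- eig_at((a + b) / 2, guess)
    data.frame(kind = kind, P = (a + b) / 2, speed = em$fp$steady_speed,
               theta = em$fp$state[[1]])
  }
  real_ <- pts$eig_im < 1e-8
  for (i in seq_len(nrow(pts) - 1)) {
    if (!(real_[i] && real_[i + 1])) next
    if ((pts$eig1[i] + 1) * (pts$eig1[i + 1] + 1) < 0)
      res[[length(res) + 1]] <- refine(i, 1, -1, "period_doubling")
    if ((pts$eig2[i] - 1) * (pts$eig2[i + 1] - 1) < 0)
      res[[length(res) + 1]] <- refine(i, 2, 1, "transcritical")
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(kind = character(), P = numeric(), speed = numeric(),
                  theta = numeric())
}

#' @export
print.gait_branch <- function(x, ...) {
  cat(sprintf("<gait_branch> %s-period family: %d points, P in [%.4g, %.4g]\n",
              x$branch, nrow(x$points), min(x$points$P), max(x$points$P)))
  if (nrow(x$bifurcations)) {
    for (i in seq_len(nrow(x$bifurcations)))
      cat(sprintf("  %s at P* = %.6g (V* = %.6g)\n",
                  x$bifurcations$kind[i], x$bifurcations$P[i],
                  x$bifurcations$speed[i]))
  }
  invisible(x)
}

#' Push-off realising a target steady speed on a gait branch
#'
#' Inverts the branch's speed/push-off relation by monotone interpolation of
#' the continuation points followed by exact root refinement on the
#' fixed-point speed.
#'
#' @param branch_obj a [continue_branch()] result.
#' @param V_star target steady-state step speed.
#' @param control a [walker_control()].
#' @return A `gait_fixed_point` whose `steady_speed` equals `V_star` (to
#'   root tolerance), with the realising `pushoff`.
#' @export
speed_to_pushoff <- function(branch_obj, V_star, control = walker_control()) {
  pts <- branch_obj$points
  if (V_star < min(pts$speed) || V_star > max(pts$speed))
    stop("target speed ", V_star, " outside the continued branch range [",
         round(min(pts$speed), 5), ", ", round(max(pts$speed), 5), "]")
  o <- order(pts$speed)
  P0 <- approx(pts$speed[o], pts$P[o], xout = V_star, ties = "ordered")$y
  branch_guess <- function(P) {
    i0 <- which.min(abs(pts$P - P))
    c(pts$theta[i0], pts$thetadot[i0])
  }
  f <- function(P) find_fixed_point(P, branch_guess(P), control)$steady_speed - V_star
  dP <- max(2e-3, 2 * abs(pts$P[2] - pts$P[1]))
  lo <- max(min(pts$P), P0 - dP); hi <- min(max(pts$P), P0 + dP)
  r <- uniroot(f, c(lo, hi), tol = 1e-10, extendInt = "yes")
  find_fixed_point(r$root, branch_guess(r$root), control)
}
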