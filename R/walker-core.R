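#' Numerical settings for the walker's hybrid dynamics
#'
#' Collects integration tolerances and model limits used by every operation
#' that simulates the walker. All quantities are dimensionless: lengths are
#' scaled by leg length, time by sqrt(leg length / g), impulses by
#' m * sqrt(g * leg length).
#'
#' @param reltol,abstol relative/absolute tolerances of the adaptive
#'   Dormand-Prince stance integrator. The defaults are tight because region
#'   areas are later quoted to four significant digits.
#' @param tcap stance-time cap; a stance that never reaches a legitimate heel
#'   strike within `tcap` time units is classified as stuck.
#' @param fall_angle stance angle at which the walker is declared fallen
#'   (hip at ground level).
#' @param theta_cap largest stance angle admitted to any region analysis;
#'   covers the range of stance angles observed in human walking.
#' @param pushoff_cap search cap for the speed regulator's push-off
#'   optimization where the actuation upper limit is unbounded.
#'
#' @return A list of class `walker_control`.
#' @export
walker_control <- function(reltol = 1e-10, abstol = 1e-12, tcap = 50,
                           fall_angle = -pi / 2, theta_cap = 0.85,
                           pushoff_cap = 2) {
  stopifnot(reltol > 0, abstol > 0, tcap > 0, fall_angle < 0,
            theta_cap > 0, pushoff_cap > 0)
  structure(list(reltol = reltol, abstol = abstol, tcap = tcap,
                 fall_angle = fall_angle, theta_cap = theta_cap,
                 pushoff_cap = pushoff_cap),
            class = "walker_control")
}

#' Post-heel-strike section state of the walker
#'
#' The walker's state just after heel strike is fully described by the stance
#' leg angle and its rate; these are the coordinates of the step-to-step
#' Poincare map. Feasible states have `theta_plus >= 0` and
#' `thetadot_plus <= 0`.
#'
#' @param theta_plus stance angle just after heel strike (rad).
#' @param thetadot_plus stance angular rate just after heel strike.
#' @return An object of class `walker_state` (named numeric of length 2).
#' @export
walker_state <- function(theta_plus, thetadot_plus) {
  stopifnot(is.finite(theta_plus), is.finite(thetadot_plus))
  if (theta_plus < 0 || thetadot_plus > 0)
    stop("infeasible state: need theta_plus >= 0 and thetadot_plus <= 0")
  structure(c(theta_plus = theta_plus, thetadot_plus = thetadot_plus),
            class = "walker_state")
}

as_walker_state <- function(x) {
  if (inherits(x, "walker_state")) return(x)
  walker_state(x[[1]], x[[2]])
}

#' @export
print.walker_state <- function(x, ...) {
  cat(sprintf("<walker_state> theta+ = %.6g, thetadot+ = %.6g\n",
              x[[1]], x[[2]]))
  invisible(x)
}

#' Integrate one stance phase to the next legitimate heel strike
#'
#' Integrates the stance-phase dynamics (stance leg an inverted pendulum,
#' `theta'' = sin(theta)`; massless swing leg
#' `phi'' = sin(theta) + (thetadot^2 - cos(theta)) sin(phi)`) from the section
#' state until the first legitimate heel strike, i.e. the root of
#' `phi - 2 theta` at which `theta <= 0`, `thetadot <= 0` and
#' `phidot >= 2 thetadot`. The spurious mid-swing crossing where the legs pass
#' each other (foot scuffing) fails the rate condition and is skipped.
#'
#' @param state a [walker_state()] (or coercible pair).
#' @param control a [walker_control()].
#' @return On success, a list of class `pre_impact_state` with fields
#'   `theta_minus`, `thetadot_minus`, `phi_minus`, `phidot_minus`,
#'   `step_time`, `min_grf` (smallest stance ground-reaction margin
#'   `cos(theta) - thetadot^2` seen along the trajectory) and `energy_drift`.
#'   On failure, a list of class `stance_failure` with field `failure` equal
#'   to `"stuck_before_vertical"` (rate reaches zero before the stance leg
#'   passes vertical) or `"falls_forward"`.
#' @export
integrate_stance <- function(state, control = walker_control()) {
  x <- as_walker_state(state)
  r <- cpp_stance(x[[1]], x[[2]], control$reltol, control$abstol,
                  control$tcap, control$fall_angle)
  code <- as.integer(r[["code"]])
  if (code != 0L) {
    return(structure(list(failure = failure_label(code),
                          step_time = r[["tau"]]),
                     class = "stance_failure"))
  }
  structure(list(theta_minus = r[["theta_minus"]],
                 thetadot_minus = r[["thetadot_minus"]],
                 phi_minus = r[["phi_minus"]],
                 phidot_minus = r[["phidot_minus"]],
                 step_time = r[["tau"]],
                 min_grf = r[["min_grf"]],
                 energy_drift = r[["energy_drift"]]),
            class = "pre_impact_state")
}

is_stance_failure <- function(x) inherits(x, "stance_failure")

assert_pre_impact <- function(pre, tol = 1e-8) {
  stopifnot(inherits(pre, "pre_impact_state"))
  ok <- pre$theta_minus <= tol && pre$thetadot_minus <= tol &&
    abs(pre$phi_minus - 2 * pre$theta_minus) <= 1e-6 &&
    pre$phidot_minus >= 2 * pre$thetadot_minus - tol
  if (!ok) stop("pre-impact state violates the heel-strike legitimacy conditions")
  invisible(pre)
}

#' Impulsive heel-strike map with push-off
#'
#' Applies the instantaneous double-support transition: the push-off impulse
#' `P` acts along the trailing leg just before heel strike, then the impact
#' redirects the hip velocity. Across heel strikes
#' `theta+ = -theta-` and
#' `thetadot+ = thetadot- cos(2 theta-) + P sin(2 theta-)`; the swing
#' coordinates reset to `phi+ = 2 theta+`,
#' `phidot+ = (1 - cos(2 theta-)) thetadot+`.
#'
#' @param pre a legitimate `pre_impact_state` (from [integrate_stance()]), or
#'   a list with at least `theta_minus` and `thetadot_minus`.
#' @param P push-off impulse, `P >= 0`.
#' @return A [walker_state()] with attributes `phi_plus` and `phidot_plus`.
#' @export
heelstrike_map <- function(pre, P = 0) {
  stopifnot(P >= 0)
  if (inherits(pre, "pre_impact_state")) assert_pre_impact(pre)
  r <- cpp_heelstrike(pre$theta_minus, pre$thetadot_minus, P)
  # exact impact identity for the angle (assignment, not computation); the
  # rate may be positive for an over-large P -- feasibility is the caller's
  # concern (checked by step_map), so no clamping here
  st <- structure(c(theta_plus = -pre$theta_minus,
                    thetadot_plus = r[["thetadot_plus"]]),
                  class = "walker_state")
  attr(st, "phi_plus") <- 2 * st[[1]]
  attr(st, "phidot_plus") <- (1 - cos(2 * pre$theta_minus)) * r[["thetadot_plus"]]
  st
}

#' Admissible push-off interval at an impending heel strike
#'
#' The push-off cannot lift the walker off the ground while the swing foot's
#' heel strike is impending, which caps it at
#' `p_max = thetadot- tan(2 theta-)` for `-pi/4 < theta- <= 0` and leaves it
#' unbounded for steeper pre-impact angles; conversely the stance foot must
#' lift off after push-off, requiring
#' `p_min = -thetadot- cot(2 theta-)` for `theta- <= -pi/4` and zero
#' otherwise.
#'
#' @inheritParams heelstrike_map
#' @return A list of class `pushoff_limits` with `p_min` and `p_max`
#'   (`p_max` may be `Inf`).
#' @export
pushoff_limits <- function(pre) {
  if (inherits(pre, "pre_impact_state")) assert_pre_impact(pre)
  r <- cpp_pushoff_limits(pre$theta_minus, pre$thetadot_minus)
  structure(list(p_min = r[["p_min"]], p_max = r[["p_max"]]),
            class = "pushoff_limits")
}

#' Ground-reaction-force non-negativity checks
#'
#' The stance-foot ground reaction force is smallest either just after or just
#' before heel strike, so its non-negativity over the whole stance phase is
#' certified by the two endpoint conditions
#' `cos(theta+) - (thetadot+)^2 >= 0` and `cos(theta-) - (thetadot-)^2 >= 0`.
#'
#' @param state the section state beginning the step.
#' @param pre the pre-impact state ending it (optional; `NA` returned if
#'   missing).
#' @return Named logical vector `c(start = , end = )`.
#' @export
grf_ok <- function(state, pre = NULL) {
  x <- as_walker_state(state)
  start <- cos(x[[1]]) - x[[2]]^2 >= 0
  end <- if (is.null(pre)) NA else
    cos(pre$theta_minus) - pre$thetadot_minus^2 >= 0
  c(start = start, end = end)
}

#' One step of the hybrid Poincare map
#'
#' Composes stance integration, the push-off feasibility check, the
#' heel-strike map, and the ground-reaction checks into one application of the
#' step-to-step map `F(x; P)`. The step length is the distance between the
#' feet at heel strike, `L = 2 sin(theta+_next)` for unit legs, and the step
#' speed is `V = L / tau`.
#'
#' @inheritParams integrate_stance
#' @param P push-off impulse applied just before this step's heel strike.
#' @return A list of class `step_outcome` with fields `next_state`,
#'   `pre_impact`, `pushoff`, `step_time`, `step_length`, `step_speed`,
#'   `min_grf`, and `failure` (one of `"none"`, `"stuck_before_vertical"`,
#'   `"falls_forward"`, `"grf_violation_start"`, `"grf_violation_end"`,
#'   `"pushoff_infeasible"`). Failures short-circuit: fields after the failing
#'   stage are `NULL`.
#' @export
step_map <- function(state, P = 0, control = walker_control()) {
  x <- as_walker_state(state)
  stopifnot(P >= 0)
  r <- cpp_step(x[[1]], x[[2]], P, control$reltol, control$abstol,
                control$tcap, control$fall_angle)
  code <- as.integer(r[["code"]])
  pre <- if (!is.na(r[["theta_minus"]]))
    structure(list(theta_minus = r[["theta_minus"]],
                   thetadot_minus = r[["thetadot_minus"]],
                   phi_minus = 2 * r[["theta_minus"]],
                   phidot_minus = r[["phidot_minus"]],
                   step_time = r[["tau"]],
                   min_grf = r[["min_grf"]],
                   energy_drift = r[["energy_drift"]]),
              class = "pre_impact_state")
  nxt <- if (code == 0L) {
    st <- walker_state(0, 0)
    st[1] <- -pre$theta_minus          # exact impact identity, no rounding
    st[2] <- r[["thetadot_next"]]
    st
  }
  structure(list(next_state = nxt, pre_impact = pre, pushoff = P,
                 step_time = r[["tau"]], step_length = r[["step_length"]],
                 step_speed = r[["step_speed"]], min_grf = r[["min_grf"]],
                 failure = failure_label(code)),
            class = "step_outcome")
}

#' @export
print.step_outcome <- function(x, ...) {
  if (x$failure == "none") {
    cat(sprintf(
      "<step_outcome> ok: next (%.6g, %.6g), tau = %.6g, L = %.6g, V = %.6g, P = %.4g\n",
      x$next_state[[1]], x$next_state[[2]], x$step_time, x$step_length,
      x$step_speed, x$pushoff))
  } else {
    cat(sprintf("<step_outcome> failure: %s\n", x$failure))
  }
  invisible(x)
}

#' Step speed attained from a state
#'
#' The speed of the single step taken from `state` (a function of the state
#' alone: the push-off at the step's end does not affect its own duration or
#' length).
#'
#' @inheritParams integrate_stance
#' @return Step speed, or `NA` if the stance fails.
#' @export
step_speed_of <- function(state, control = walker_control()) {
  pre <- integrate_stance(state, control)
  if (is_stance_failure(pre)) return(NA_real_)
  2 * sin(-pre$theta_minus) / pre$step_time
}
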