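#' Specification of a step-to-step speed regulator
#'
#' The regulator picks, at every step, the push-off minimising the squared
#' discrepancy between the next step's speed and a target `V*`, then clips
#' the minimiser to the actuation limits. It uses no information about the
#' viability kernel's boundaries.
#'
#' @param target_speed target step speed `V*` (> 0).
#' @param tolerance optimiser tolerance on the push-off.
#' @param pushoff_cap search cap where the actuation upper limit is
#'   unbounded.
#' @return A list of class `regulator_spec`.
#' @export
regulator_spec <- function(target_speed, tolerance = 1e-10, pushoff_cap = 2) {
  stopifnot(target_speed > 0, tolerance > 0, pushoff_cap > 0)
  structure(list(target_speed = target_speed, tolerance = tolerance,
                 pushoff_cap = pushoff_cap),
            class = "regulator_spec")
}

#' Speed of the step after next, as a function of the current push-off
#'
#' Integrates the current stance, applies `P` at its heel strike, and
#' integrates the following stance: the returned value is the next step's
#' speed `V_{k+1}`, which depends on the current state and `P` only through
#' the post-impact state.
#'
#' @inheritParams integrate_stance
#' @param P push-off applied at the end of the current step.
#' @return `V_{k+1}`, or `NA` with attribute `failure` if either stance
#'   fails.
#' @export
next_step_speed <- function(state, P, control = walker_control()) {
  out <- step_map(state, P, control)
  if (out$failure != "none") {
    return(structure(NA_real_, failure = out$failure))
  }
  v <- step_speed_of(out$next_state, control)
  if (is.na(v)) return(structure(NA_real_, failure = "next_stance_failed"))
  v
}

#' One-step-optimal push-off of the speed regulator
#'
#' Minimises `(V_{k+1}(x_k; P) - V*)^2` over `P >= 0` by a coarse scan
#' followed by golden-section refinement (each cost evaluation applies the
#' heel-strike map and integrates the next stance); among cost minimisers the
#' smallest push-off is taken, and the result is clipped to the admissible
#' interval `[p_min, p_max]`.
#'
#' @inheritParams integrate_stance
#' @param spec a [regulator_spec()].
#' @return A list with `p_opt` (unclipped minimiser), `p_applied` (clipped),
#'   `p_min`, `p_max`, `saturated` (`"none"`, `"min"` or `"max"`), or a
#'   `stance_failure` if the current stance fails.
#' @export
optimal_pushoff <- function(state, spec, control = walker_control()) {
  pre <- integrate_stance(state, control)
  if (is_stance_failure(pre)) return(pre)
  r <- cpp_regulator_direct(pre$theta_minus, pre$thetadot_minus,
                            spec$target_speed, spec$pushoff_cap,
                            control$reltol, control$abstol, control$tcap,
                            control$fall_angle)
  if (is.na(r[["p_opt"]]))
    return(structure(list(failure = "pushoff_infeasible"),
                     class = "stance_failure"))
  saturated <- if (r[["p_opt"]] < r[["p_min"]]) "min"
  else if (r[["p_opt"]] > r[["p_max"]]) "max"
  else "none"
  list(p_opt = r[["p_opt"]], p_applied = r[["p_applied"]],
       p_min = r[["p_min"]], p_max = r[["p_max"]], saturated = saturated,
       cost = r[["cost"]],
       # an interior minimiser either attains the target speed exactly or
       # sits at a stationary point of the speed in the impulse (the two
       # branches of the goal-equivalent manifold)
       attained = is.finite(r[["cost"]]) && r[["cost"]] < 1e-12)
}

#' One speed-regulated step
#'
#' Applies [step_map()] with the push-off chosen by [optimal_pushoff()].
#'
#' @inheritParams optimal_pushoff
#' @return A `step_outcome` (with the applied push-off recorded); failures
#'   propagate as in [step_map()].
#' @export
regulated_step <- function(state, spec, control = walker_control()) {
  p <- optimal_pushoff(state, spec, control)
  if (is_stance_failure(p)) {
    out <- structure(list(next_state = NULL, pre_impact = NULL,
                          pushoff = NA_real_, step_time = NA_real_,
                          step_length = NA_real_, step_speed = NA_real_,
                          min_grf = NA_real_, failure = p$failure),
                     class = "step_outcome")
    return(out)
  }
  out <- step_map(state, p$p_applied, control)
  out$saturated <- p$saturated
  out
}

#' Target-speed (goal-equivalent) manifold
#'
#' The set of states onto which an unsaturated regulated step maps: the locus
#' where the state's own step speed equals the target (`V = V*`), continued
#' with the saturated branch where the target is unattainable and the
#' optimum sits at `dV/dP = 0` (equivalently, the extremum of speed over the
#' post-impact rate). Constructed per stance-angle column by root finding
#' (predictor from the neighbouring column), since the speed map is a
#' function of the state.
#'
#' @param V_star target step speed.
#' @param control a [walker_control()].
#' @param theta_range range of stance angles to cover.
#' @param n number of columns.
#' @return A data frame of class `target_speed_manifold` with columns
#'   `theta_plus`, `thetadot_plus`, `speed`, `branch`
#'   (`"target_speed"` or `"saturated"`); columns where no wedge state
#'   attains a speed near the target are absent.
#' @export
build_target_speed_manifold <- function(V_star, control = walker_control(),
                                        theta_range = c(0.02, 0.84),
                                        n = 150) {
  ths <- seq(theta_range[1], theta_range[2], length.out = n)
  speed_at <- function(th, w) {
    r <- cpp_stance(th, w, control$reltol, control$abstol, control$tcap,
                    control$fall_angle)
    if (as.integer(r[["code"]]) != 0L) return(NA_real_)
    2 * sin(-r[["theta_minus"]]) / r[["tau"]]
  }
  rows <- list()
  for (th in ths) {
    ol <- omega_low(th); oh <- omega_high(th, control)
    eps <- 1e-4 * (ol - oh)
    ws <- seq(ol - eps, oh + eps, length.out = 25)
    vs <- vapply(ws, function(w) speed_at(th, w), numeric(1))
    valid <- which(!is.na(vs))
    if (length(valid) < 3) next
    i_cross <- valid[which(diff(sign(vs[valid] - V_star)) != 0)]
    if (length(i_cross)) {
      i <- i_cross[1]
      j <- valid[match(i, valid) + 1]
      r <- uniroot(function(w) speed_at(th, w) - V_star, c(ws[i], ws[j]),
                   tol = 1e-12)
      rows[[length(rows) + 1L]] <-
        data.frame(theta_plus = th, thetadot_plus = r$root,
                   speed = speed_at(th, r$root), branch = "target_speed")
    } else if (max(vs[valid]) < V_star) {
      # saturated branch: extremum of speed over the rate
      o <- optimize(function(w) speed_at(th, w),
                    range(ws[valid]), maximum = TRUE, tol = 1e-10)
      rows[[length(rows) + 1L]] <-
        data.frame(theta_plus = th, thetadot_plus = o$maximum,
                   speed = o$objective, branch = "saturated")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("target_speed_manifold", class(out))
  attr(out, "target_speed") <- V_star
  out
}
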