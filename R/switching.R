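#' Hierarchical task-switching policy
#'
#' Bundles an ordered set of target speeds, their precomputed speed-regulated
#' basins (all on one subgrid of the kernel grid), and the final task target.
#' At every step the walker selects one target speed -- a "task switch" --
#' from this small collection, so recovery from a large disturbance only
#' requires traversing overlapping basins back to the final target's basin.
#'
#' @param targets ordered vector of target speeds (slowest to fastest).
#' @param basins list of [estimate_basin()] results aligned with `targets`.
#' @param gaits list of `gait_fixed_point`s aligned with `targets`.
#' @param final_target the task's own target speed (must be in `targets`).
#' @param kernel the [viability_kernel()] the basins were estimated on.
#' @return An object of class `switch_policy`.
#' @export
switch_policy <- function(targets, basins, gaits, final_target, kernel) {
  stopifnot(length(targets) == length(basins),
            length(targets) == length(gaits),
            final_target %in% targets,
            !is.unsorted(targets))
  g0 <- basins[[1]]$grid
  for (b in basins)
    if (!identical(dim(b$membership), c(g0$n_sc, g0$n_theta)))
      stop("basins must share one subgrid")
  structure(list(targets = targets, basins = basins, gaits = gaits,
                 final_target = final_target,
                 final_index = match(final_target, targets),
                 kernel = kernel, grid = g0,
                 omlow = basins[[1]]$omlow, omhigh = basins[[1]]$omhigh),
            class = "switch_policy")
}

#' @export
print.switch_policy <- function(x, ...) {
  cat(sprintf("<switch_policy> %d targets {%s}; final V* = %g\n",
              length(x$targets), paste(signif(x$targets, 3), collapse = ", "),
              x$final_target))
  invisible(x)
}

# nearest-cell basin membership lookup for an off-grid state
policy_membership <- function(policy, state) {
  g <- policy$grid
  th <- state[[1]]; thd <- state[[2]]
  j <- round(th / g$dtheta)
  if (j < 1 || j > g$n_theta) return(rep(FALSE, length(policy$basins)))
  sc <- (thd - policy$omlow[j]) / (policy$omlow[j] - policy$omhigh[j])
  i <- round(-sc / g$dsc) + 1L
  if (i < 1 || i > g$n_sc) return(rep(FALSE, length(policy$basins)))
  vapply(policy$basins, function(b) b$membership[i, j], logical(1))
}

#' Select the target speed for the current state
#'
#' Returns the final target if the state lies in its basin; otherwise the
#' containing basin whose index is nearest the final target's (ties broken
#' toward the lower index, deterministically).
#'
#' @param state a [walker_state()].
#' @param policy a [switch_policy()].
#' @return The selected target speed (scalar).
#' @export
select_target <- function(state, policy) {
  inb <- policy_membership(policy, state)
  if (!any(inb))
    stop("state (", signif(state[[1]], 5), ", ", signif(state[[2]], 5),
         ") lies outside the policy's basin cover")
  if (inb[policy$final_index]) return(policy$final_target)
  cand <- which(inb)
  sel <- cand[which.min(abs(cand - policy$final_index))]
  policy$targets[sel]
}

#' Simulate a post-disturbance recovery episode
#'
#' Repeats target selection and one speed-regulated step until the walker's
#' state is on the final target's speed manifold inside its basin (the
#' "fast" switching phase), then continues under the final regulator while
#' it approaches the steady-state gait.
#'
#' @param state disturbed initial [walker_state()] (must be in the cover).
#' @param policy a [switch_policy()].
#' @param max_steps episode cap.
#' @param control a [walker_control()].
#' @param manifold_tol speed discrepancy below which the state counts as on
#'   the final target-speed manifold.
#' @return An object of class `recovery_trace`: data frame `steps` with
#'   columns `k`, `theta`, `thetadot`, `target`, `pushoff`, `speed`,
#'   `saturated`, plus `steps_to_final_basin`, `steps_to_final_manifold`,
#'   `failed` flag.
#' @export
simulate_recovery <- function(state, policy, max_steps = 40,
                              control = NULL, manifold_tol = 1e-6) {
  if (is.null(control)) control <- policy$kernel$control
  K <- policy$kernel
  x <- as_walker_state(state)
  rows <- list()
  k_basin <- NA_integer_; k_manifold <- NA_integer_
  failed <- FALSE
  attr_gait <- policy$gaits[[policy$final_index]]
  # one table-regulated step: identical regulator to the basin sweeps, so an
  # episode step from inside a basin is the first step of a trajectory the
  # basin estimate already certified viable
  table_step <- function(x, Vstar) {
    tr <- cpp_regulated_traj(x[[1]], x[[2]], Vstar, 2L, K$grid$dtheta,
                             K$grid$dtheta, K$omlow, K$omhigh, K$speed,
                             control$pushoff_cap, control$reltol,
                             control$abstol, control$tcap, control$fall_angle,
                             K$grid$theta_max, 0L, 0)
    if (is.na(tr[1, "P"]) || !is.na(tr[1, "code"]) && tr[1, "code"] != 0)
      return(NULL)
    list(next_state = walker_state(tr[2, "theta"], tr[2, "thetadot"]),
         pushoff = tr[1, "P"], speed = tr[1, "V"],
         next_speed = tr[2, "V"])
  }
  last_tgt <- NA_real_
  cover_gaps <- 0L
  for (k in seq_len(max_steps)) {
    tgt <- tryCatch(select_target(x, policy), error = function(e) NA_real_)
    if (is.na(tgt)) {
      # no basin claims the state: with a full cover this cannot happen, but
      # a coarse membership lattice has quantization holes; the controller
      # keeps the current regulator rather than giving up mid-flight
      if (is.na(last_tgt)) { failed <- TRUE; break }
      tgt <- last_tgt
      cover_gaps <- cover_gaps + 1L
    }
    last_tgt <- tgt
    out <- table_step(x, tgt)
    if (is.null(out)) { failed <- TRUE; break }
    rows[[k]] <- data.frame(k = k, theta = x[[1]], thetadot = x[[2]],
                            target = tgt, pushoff = out$pushoff,
                            speed = out$speed)
    x <- out$next_state
    inb <- policy_membership(policy, x)
    if (is.na(k_basin) && inb[policy$final_index]) k_basin <- k
    if (is.na(k_manifold) && tgt == policy$final_target &&
        inb[policy$final_index] && !is.na(out$next_speed) &&
        abs(out$next_speed - policy$final_target) < manifold_tol)
      k_manifold <- k
    # settled on the steady-state gait
    if (!is.na(k_manifold) &&
        max(abs(unclass(x) - unclass(attr_gait$state))) < 1e-9) break
  }
  structure(list(steps = do.call(rbind, rows), final_state = x,
                 steps_to_final_basin = k_basin,
                 steps_to_final_manifold = k_manifold,
                 cover_gaps = cover_gaps,
                 failed = failed),
            class = "recovery_trace")
}

#' @export
print.recovery_trace <- function(x, ...) {
  n <- if (is.null(x$steps)) 0 else nrow(x$steps)
  cat(sprintf(
    "<recovery_trace> %d steps; to final basin: %s; to final manifold: %s%s\n",
    n, x$steps_to_final_basin, x$steps_to_final_manifold,
    if (x$failed) " [FAILED]" else ""))
  invisible(x)
}

#' Stress-test a switching policy over random kernel states
#'
#' Samples states uniformly (by area) from the covered kernel, runs a
#' recovery episode from each toward the policy's final target, and
#' summarises success, episode lengths, and any viability violations
#' (expected none).
#'
#' @param policy a [switch_policy()].
#' @param n_samples number of sampled start states.
#' @param seed RNG seed.
#' @param max_steps per-episode cap.
#' @param control a [walker_control()].
#' @return A list of class `stress_report` with `success_rate`,
#'   `n_outside_cover`, `steps_to_manifold` (vector), `violations`.
#' @export
stress_test <- function(policy, n_samples = 100, seed = 1, max_steps = 40,
                        control = NULL) {
  if (is.null(control)) control <- policy$kernel$control
  g <- policy$grid
  cover <- Reduce(`|`, lapply(policy$basins, function(b) b$membership))
  idx <- which(cover)
  jj <- (idx - 1L) %/% g$n_sc + 1L
  wgt <- (policy$omlow - policy$omhigh)[jj]
  set.seed(seed)
  picks <- sample(seq_along(idx), n_samples, replace = TRUE, prob = wgt)
  ii <- (idx[picks] - 1L) %% g$n_sc + 1L
  jj <- (idx[picks] - 1L) %/% g$n_sc + 1L
  # covered lattice points (cell centres): membership is resolved at cell
  # resolution, so sampling stays on the lattice
  th <- g$theta[jj]
  w <- policy$omlow[jj] + g$sc[ii] * (policy$omlow[jj] - policy$omhigh[jj])
  n_ok <- 0L; n_out <- 0L
  steps_m <- rep(NA_integer_, n_samples)
  violations <- 0L
  for (s in seq_len(n_samples)) {
    x <- tryCatch(walker_state(th[s], w[s]), error = function(e) NULL)
    if (is.null(x) || !any(policy_membership(policy, x))) {
      n_out <- n_out + 1L
      next
    }
    tr <- simulate_recovery(x, policy, max_steps, control)
    if (!tr$failed && !is.na(tr$steps_to_final_manifold)) {
      n_ok <- n_ok + 1L
      steps_m[s] <- tr$steps_to_final_manifold
    } else if (tr$failed) {
      violations <- violations + 1L
    }
  }
  structure(list(success_rate = n_ok / (n_samples - n_out),
                 n_outside_cover = n_out,
                 steps_to_manifold = steps_m[!is.na(steps_m)],
                 violations = violations, n_samples = n_samples,
                 seed = seed),
            class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  cat(sprintf(
    "<stress_report> success %.1f%% of %d in-cover samples; median steps to manifold %s; %d violations\n",
    100 * x$success_rate, x$n_samples - x$n_outside_cover,
    median(x$steps_to_manifold), x$violations))
  invisible(x)
}
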