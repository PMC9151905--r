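# Shared, lazily-built fixtures. The heavy objects (kernel at the default
# 850 x 201 grid, continued gait branches, basin sets) are computed once per
# test run and memoised here; everything is deterministic.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_control <- function() walker_control()

fx_kernel <- function() fx_memo("kernel", function() {
  v1 <- one_step_viable_region(grid_spec(850, 201), fx_control())
  viability_kernel(v1)
})

fx_v1 <- function() fx_memo("v1", function() {
  # the kernel object carries all v1 caches; keep a separate v1 for area
  one_step_viable_region(grid_spec(850, 201), fx_control())
})

fx_unreachable <- function() fx_memo("unreachable", function() {
  unreachable_set(fx_kernel())
})

fx_branch_long <- function() fx_memo("branch_long", function() {
  continue_branch("long", c(5e-4, 0.85), 2e-3, fx_control())
})

fx_branch_short <- function() fx_memo("branch_short", function() {
  continue_branch("short", c(5e-4, 0.85), 2e-3, fx_control())
})

fx_gait_at_P <- function(P) {
  pts <- fx_branch_long()$points
  j <- which.min(abs(pts$P - P))
  find_fixed_point(P, c(pts$theta[j], pts$thetadot[j]), fx_control())
}

fx_gait_at_V <- function(V) speed_to_pushoff(fx_branch_long(), V, fx_control())

# six open-loop basins at the study push-offs (stride 2 for accuracy)
fx_openloop_basins <- function() fx_memo("openloop_basins", function() {
  lapply(c(0.001, 0.01, 0.05, 0.1, 0.1325, 0.288), function(P)
    estimate_basin(fx_kernel(), open_loop(P), fx_gait_at_P(P),
                   stride = c(2L, 2L)))
})

# six regulated basins at the matching steady speeds (coarser stride)
fx_regulated_basins <- function() fx_memo("regulated_basins", function() {
  lapply(c(0.001, 0.01, 0.05, 0.1, 0.1325, 0.288), function(P) {
    fp <- fx_gait_at_P(P)
    estimate_basin(fx_kernel(), speed_regulated(fp$steady_speed), fp,
                   stride = c(5L, 4L))
  })
})

# the five-speed switching cover
fx_cover_basins <- function() fx_memo("cover_basins", function() {
  lapply(c(0.016, 0.051, 0.113, 0.178, 0.251), function(V) {
    fp <- fx_gait_at_V(V)
    estimate_basin(fx_kernel(), speed_regulated(V), fp, stride = c(5L, 4L))
  })
})

fx_policy <- function() fx_memo("policy", function() {
  speeds <- c(0.016, 0.051, 0.113, 0.178, 0.251)
  gaits <- lapply(speeds, fx_gait_at_V)
  switch_policy(speeds, fx_cover_basins(), gaits, 0.113, fx_kernel())
})

# deterministic in-wedge sample states (mid-band fractions)
fx_wedge_states <- function(n, seed = 42, th_range = c(0.05, 0.8),
                            sc_range = c(-0.9, -0.1)) {
  set.seed(seed)
  th <- runif(n, th_range[1], th_range[2])
  sc <- runif(n, sc_range[1], sc_range[2])
  ol <- omega_low(th)
  oh <- omega_high(th, fx_control())
  cbind(theta = th, thetadot = ol + sc * (ol - oh))
}
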