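#' Run configuration for the full analysis pipeline
#'
#' Collects every tunable of the pipeline with validated defaults. The
#' reference-resolution settings of the headline analysis (42500 x 1002 grid,
#' 50 open-loop / 25 regulated basin steps, stance-angle cap 0.85) are the
#' documented defaults of their fields; the default grid here is the
#' desk-scale 850 x 201 used throughout the package's tests.
#'
#' @param n_theta,n_sc analysis grid resolution (scaled state space).
#' @param theta_cap largest stance angle analysed.
#' @param openloop_steps,regulated_steps basin simulation horizons.
#' @param target_speeds speeds of the switching policy's regulators.
#' @param final_target the nominal task speed for the recovery demo.
#' @param basin_stride subsampling of basin start points `c(theta, rate)`.
#' @param seed RNG seed for stress sampling.
#' @param control a [walker_control()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(n_theta = 850, n_sc = 201, theta_cap = 0.85,
                       openloop_steps = 50, regulated_steps = 25,
                       target_speeds = c(0.016, 0.051, 0.113, 0.178, 0.251),
                       final_target = 0.113, basin_stride = c(2L, 2L),
                       seed = 1L, control = walker_control()) {
  stopifnot(n_theta >= 50, n_sc >= 21, theta_cap > 0.2,
            openloop_steps >= 1, regulated_steps >= 1,
            all(target_speeds > 0), !is.unsorted(target_speeds),
            final_target %in% target_speeds || final_target > 0,
            length(basin_stride) == 2)
  structure(list(n_theta = as.integer(n_theta), n_sc = as.integer(n_sc),
                 theta_cap = theta_cap,
                 openloop_steps = as.integer(openloop_steps),
                 regulated_steps = as.integer(regulated_steps),
                 target_speeds = target_speeds, final_target = final_target,
                 basin_stride = as.integer(basin_stride),
                 seed = as.integer(seed), control = control),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole analysis: 1-step viable region, viability kernel,
#' unreachable subset, gait-family continuation with bifurcations, basins of
#' the switching policy's target speeds, coverage, and a recovery stress
#' sample. Writes CSV/JSON artifacts when `out_dir` is given; always returns
#' the summary.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created), or `NULL` for no files.
#' @param quiet suppress progress messages.
#' @return A list of class `pipeline_result` with all stage objects and a
#'   `summary` list of headline scalars.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3]
  stage <- function(lab, expr) {
    t1 <- proc.time()[3]
    v <- force(expr)
    say("[%5.1fs] %s", proc.time()[3] - t1, lab)
    v
  }
  ctl <- config$control
  grid <- grid_spec(config$n_theta, config$n_sc, config$theta_cap)
  v1 <- stage("1-step viable region", one_step_viable_region(grid, ctl))
  kernel <- stage("viability kernel", viability_kernel(v1))
  unreach <- stage("unreachable subset", unreachable_set(kernel))
  branch_long <- stage("long-period continuation",
                       continue_branch("long", c(5e-4, 0.85), 2e-3, ctl))
  branch_short <- stage("short-period continuation",
                        continue_branch("short", c(5e-4, 0.85), 2e-3, ctl))
  gaits <- lapply(config$target_speeds, function(v)
    speed_to_pushoff(branch_long, v, ctl))
  basins <- stage("speed-regulated basins", lapply(seq_along(gaits), function(i)
    estimate_basin(kernel, speed_regulated(config$target_speeds[i]),
                   gaits[[i]], n_steps = config$regulated_steps,
                   stride = config$basin_stride, control = ctl)))
  cov <- coverage(basins)
  policy <- switch_policy(config$target_speeds, basins, gaits,
                          config$final_target, kernel)
  stress <- stage("recovery stress sample",
                  stress_test(policy, n_samples = 50, seed = config$seed,
                              control = ctl))
  bifs <- branch_long$bifurcations
  pd <- bifs$P[bifs$kind == "period_doubling"][1]
  tc <- bifs[bifs$kind == "transcritical", , drop = FALSE]
  summary <- list(
    grid = c(config$n_theta, config$n_sc),
    v1_area = v1$area,
    kernel_area = kernel$area,
    kernel_fraction_of_v1 = 100 * kernel$area_ratio,
    kernel_converged_at = kernel$converged_at,
    unreachable_fraction = 100 * unreach$fraction_of_kernel,
    unreachable_components = unreach$n_major_components,
    period_doubling_P = pd,
    transcritical_P = if (nrow(tc)) tc$P[1] else NA_real_,
    transcritical_V = if (nrow(tc)) tc$speed[1] else NA_real_,
    basin_fractions = vapply(basins, function(b) b$area_fraction_of_kernel,
                             numeric(1)),
    union_fraction = cov$union_fraction,
    stress_success_rate = stress$success_rate,
    elapsed_s = proc.time()[3] - t0)
  res <- structure(list(config = config, v1 = v1, kernel = kernel,
                        unreachable = unreach, branch_long = branch_long,
                        branch_short = branch_short, gaits = gaits,
                        basins = basins, coverage = cov, policy = policy,
                        stress = stress, summary = summary),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  kernel / V1 area: %.2f%% (converged at %d)\n",
              s$kernel_fraction_of_v1, s$kernel_converged_at))
  cat(sprintf("  unreachable: %.2f%% of kernel (%d components)\n",
              s$unreachable_fraction, s$unreachable_components))
  cat(sprintf("  period doubling P* = %.5f; transcritical V* = %.5f\n",
              s$period_doubling_P, s$transcritical_V))
  cat(sprintf("  basin fractions: %s%%; union %.2f%%\n",
              paste(sprintf("%.1f", s$basin_fractions), collapse = ", "),
              s$union_fraction))
  invisible(x)
}

# ---- writers ---------------------------------------------------------------

#' Write pipeline artifacts to a directory
#'
#' CSV files for curves/regions/branches (all columns in dimensionless model
#' units) and a JSON summary.
#'
#' @param res a `pipeline_result`.
#' @param out_dir target directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_region_csv(res$kernel, file.path(out_dir, "kernel_membership.csv"))
  write_region_csv(res$v1, file.path(out_dir, "v1_membership.csv"))
  utils::write.csv(res$branch_long$points,
                   file.path(out_dir, "branch_long.csv"), row.names = FALSE)
  utils::write.csv(res$branch_short$points,
                   file.path(out_dir, "branch_short.csv"), row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a gridded region as CSV
#'
#' Long-format rows `(theta_plus, thetadot_scaled, member)`; units are
#' dimensionless model units (angles in rad).
#'
#' @param region a `region_estimate`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(region, path) {
  g <- region$grid
  idx <- which(region$membership)
  df <- data.frame(
    theta_plus = g$theta[(idx - 1L) %/% g$n_sc + 1L],
    thetadot_scaled = g$sc[(idx - 1L) %% g$n_sc + 1L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate cached coarse fixtures for fast downstream runs
#'
#' Runs the pipeline at a reduced resolution and writes its artifacts; the
#' `ci` level finishes in about a minute, `full` at the package's default
#' resolution.
#'
#' @param level `"ci"` or `"full"`.
#' @param dir output directory.
#' @return The `pipeline_result`, invisibly.
#' @export
make_fixtures <- function(level = c("ci", "full"), dir = tempfile("viabwalk")) {
  level <- match.arg(level)
  cfg <- if (level == "ci")
    run_config(n_theta = 210, n_sc = 51, basin_stride = c(2L, 2L))
  else run_config()
  res <- run_pipeline(cfg, out_dir = dir, quiet = TRUE)
  invisible(res)
}
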