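#' Correlated-random-walk parameters
#'
#' Parameter block for the walk: fixed step length, Gaussian turning angles
#' (mean `turn_mean`, SD `turn_sd`), the overall path-length cap, and the
#' boundary-collision rule. When a proposed step would leave the lake the
#' heading is redrawn with an inflated SD
#' `turn_sd * (1 + collision_coeff * k^collision_exponent)`, where `k` counts
#' the failed attempts for that step (k = 0 on the first draw and after any
#' accepted step), so repeated collisions progressively free the walker from
#' the shoreline.
#'
#' @param step_length Step length L in meters (> 0).
#' @param turn_sd Turning-angle standard deviation, degrees (>= 0).
#' @param turn_mean Mean turning angle, degrees (default 0: no bias).
#' @param max_path_length Path-length cap in meters (>= `step_length`); the
#'   walk takes at most `floor(max_path_length / step_length)` steps.
#' @param collision_coeff Collision-inflation coefficient (default 0.1).
#' @param collision_exponent Exponent applied to the collision count k
#'   (default 2).
#' @param max_collision_retries Redraws allowed per step before the path is
#'   abandoned as `failure_retries` (default 100).
#' @param capture_mode How entry into the capture region is detected.
#'   `"segment"` and `"point"` test every proposed step before the shoreline
#'   bounce is applied (entry counts even if the step would exit the lake):
#'   on the swept segment or on the step endpoint respectively.
#'   `"accepted_segment"` and `"accepted_point"` apply the shoreline bounce
#'   first, so only in-lake steps can register a capture — the walk is
#'   generated entirely inside the polygon and the outlet check runs on the
#'   realized steps, with long steps able to overshoot the region.
#' @return An object of class `crw_params`.
#' @export
crw_params <- function(step_length, turn_sd, turn_mean = 0,
                       max_path_length, collision_coeff = 0.1,
                       collision_exponent = 2, max_collision_retries = 100L,
                       capture_mode = c("segment", "point",
                                        "accepted_segment", "accepted_point")) {
  capture_mode <- match.arg(capture_mode)
  stopifnot(is.numeric(step_length), step_length > 0,
            is.numeric(turn_sd), turn_sd >= 0,
            is.numeric(max_path_length), max_path_length >= step_length,
            collision_coeff >= 0, max_collision_retries >= 1)
  structure(list(step_length = step_length, turn_sd = turn_sd,
                 turn_mean = turn_mean, max_path_length = max_path_length,
                 collision_coeff = collision_coeff,
                 collision_exponent = collision_exponent,
                 max_collision_retries = as.integer(max_collision_retries),
                 capture_mode = capture_mode),
            class = "crw_params")
}

#' @export
print.crw_params <- function(x, ...) {
  cat(sprintf("<crw_params> L = %g m, sigma = %g deg, cap = %g km (%d steps max)\n",
              x$step_length, x$turn_sd, x$max_path_length / 1000,
              max_steps_for(x)))
  invisible(x)
}

max_steps_for <- function(params) {
  as.integer(floor(params$max_path_length / params$step_length))
}

#' Collision-inflated turning-angle SD
#'
#' The SD used for the k-th redraw after a step collided with the shoreline:
#' `sigma * (1 + coeff * k^exponent)`. Monotone non-decreasing in k; k = 0
#' gives back `sigma` unchanged.
#'
#' @param sigma Base turning-angle SD, degrees.
#' @param k Number of failed attempts so far this step (vectorized, >= 0).
#' @param coeff,exponent Inflation constants (defaults 0.1 and 2).
#' @return Inflated SD, degrees.
#' @examples
#' collision_sigma(5, 0:3)  # 5.0 5.5 7.0 9.5
#' @export
collision_sigma <- function(sigma, k, coeff = 0.1, exponent = 2) {
  stopifnot(all(k >= 0))
  sigma * (1 + coeff * k^exponent)
}

#' Draw Gaussian turning angles
#'
#' Samples from the untruncated turning-angle distribution used by the walk,
#' from the engine's own reproducible stream (so draws are bit-identical
#' across platforms for the same seed/stream).
#'
#' @param n Number of draws.
#' @param sigma SD in degrees (>= 0; 0 gives exactly 0).
#' @param mu Mean in degrees (default 0).
#' @param seed,stream Stream selectors.
#' @return Numeric vector of signed turning angles, degrees.
#' @export
draw_turn <- function(n, sigma, mu = 0, seed = 1, stream = 0) {
  stopifnot(sigma >= 0, n >= 1)
  cpp_draw_turns(as.integer(n), mu, sigma, seed, stream)
}

outcome_levels <- c("success", "failure_cap", "failure_retries")

#' Simulate one migration path
#'
#' Runs a single correlated random walk in a lake basin: starting at the
#' river mouth with the river-intercept bearing, taking fixed-length steps
#' whose headings wander by Gaussian turns, rejecting and redrawing (with
#' inflated SD) any step that would leave the lake, and terminating with
#' success when a step's segment crosses the outlet capture region, or with
#' failure when the path-length cap or the per-step retry ceiling is hit.
#' The first step's heading is a turn drawn around the initial bearing, like
#' every later step.
#'
#' @param basin A [lake_basin()]; the start point must be in the lake.
#' @param params A [crw_params()].
#' @param seed Seed for the path's random stream.
#' @param stream Substream index (used by [simulate_ensemble()]).
#' @return An object of class `crw_path`: `points` (matrix, start plus one
#'   row per accepted step), `headings` (degrees, one per step), `outcome`
#'   (`success`, `failure_cap`, or `failure_retries`), `n_steps`,
#'   `distance` (= `n_steps * step_length`, meters), `n_collisions`.
#' @export
simulate_path <- function(basin, params, seed = 1, stream = 0) {
  ens <- simulate_ensemble(basin, params, n = 1L, seed = seed,
                           keep_points = TRUE, first_stream = stream)
  path_from_ensemble(ens, 1L)
}

path_from_ensemble <- function(ens, i) {
  rec <- ens$records[i, ]
  structure(list(points = ens$paths[[i]],
                 headings = ens$headings[[i]],
                 outcome = rec$outcome,
                 n_steps = rec$n_steps,
                 distance = rec$distance_m,
                 n_collisions = rec$n_collisions,
                 params = ens$params,
                 basin_name = ens$basin_name),
            class = "crw_path")
}

#' @export
print.crw_path <- function(x, ...) {
  cat(sprintf("<crw_path> %s: %d steps (%.1f km), %d boundary collisions\n",
              x$outcome, x$n_steps, x$distance / 1000, x$n_collisions))
  invisible(x)
}

#' @export
plot.crw_path <- function(x, basin = NULL, ...) {
  if (!is.null(basin)) {
    ring <- rbind(basin$polygon$outer, basin$polygon$outer[1, ])
    plot(ring, type = "l", asp = 1, xlab = "x (m)", ylab = "y (m)", ...)
    th <- seq(0, 2 * pi, length.out = 90)
    lines(basin$capture$center[1] + basin$capture$radius * cos(th),
          basin$capture$center[2] + basin$capture$radius * sin(th), col = "red")
    lines(x$points, col = "steelblue")
  } else {
    plot(x$points, type = "l", asp = 1, xlab = "x (m)", ylab = "y (m)",
         col = "steelblue", ...)
  }
  points(x$points[1, 1], x$points[1, 2], pch = 18, col = "purple", cex = 1.3)
  invisible(x)
}

#' Simulate an ensemble of migration paths
#'
#' Runs `n` independent walks with deterministically derived per-path
#' substreams: path i uses substream `first_stream + i - 1` of the seed, so
#' the same (basin, params, n, seed) always yields a bit-identical ensemble
#' and growing `n` never perturbs earlier paths.
#'
#' @inheritParams simulate_path
#' @param n Number of paths (>= 1).
#' @param keep_points Keep full trajectories (memory-heavy for large grids;
#'   default FALSE keeps per-path records only).
#' @param first_stream Index of the first substream (default 0).
#' @return An object of class `crw_ensemble` with `records` (data.frame:
#'   `path_id`, `outcome`, `n_steps`, `distance_m`, `n_collisions`) and, if
#'   requested, `paths` / `headings` lists.
#' @export
simulate_ensemble <- function(basin, params, n, seed = 1,
                              keep_points = FALSE, first_stream = 0) {
  stopifnot(inherits(basin, "lake_basin"), inherits(params, "crw_params"),
            n >= 1)
  if (!point_in_polygon(basin$start, basin$polygon, tol = 1.0))
    stop("basin start point is outside the lake polygon", call. = FALSE)
  poly <- basin$polygon
  holes <- lapply(poly$holes %||% list(),
                  function(h) list(h[, 1], h[, 2]))
  raw <- cpp_simulate_ensemble(
    poly$outer[, 1], poly$outer[, 2], holes,
    basin$start[1], basin$start[2], basin$initial_bearing,
    basin$capture$center[1], basin$capture$center[2], basin$capture$radius,
    params$step_length, params$turn_mean, params$turn_sd,
    max_steps_for(params), params$collision_coeff, params$collision_exponent,
    params$max_collision_retries, as.integer(n), seed,
    as.integer(first_stream), keep_points, is_convex(poly),
    match(params$capture_mode %||% "segment",
          c("segment", "point", "accepted_segment", "accepted_point")) - 1L)
  records <- data.frame(
    path_id = seq_len(n),
    outcome = factor(outcome_levels[raw$outcome + 1L], levels = outcome_levels),
    n_steps = raw$n_steps,
    distance_m = raw$n_steps * params$step_length,
    n_collisions = raw$n_collisions
  )
  structure(list(records = records,
                 paths = if (keep_points) raw$points else NULL,
                 headings = if (keep_points) raw$headings else NULL,
                 params = params, basin_name = basin$name,
                 seed = seed, n = n),
            class = "crw_ensemble")
}

#' @export
print.crw_ensemble <- function(x, ...) {
  tab <- table(x$records$outcome)
  cat(sprintf("<crw_ensemble> %s: %d paths, %.1f%% success (%d cap, %d retry failures)\n",
              x$basin_name, x$n, 100 * mean(x$records$outcome == "success"),
              tab[["failure_cap"]], tab[["failure_retries"]]))
  invisible(x)
}

#' Per-step turning angles of a simulated path
#'
#' Recovers the realized signed turning angles (degrees, wrapped to
#' (-180, 180]) from a path's heading sequence; the first turn is taken
#' relative to the basin's initial bearing.
#'
#' @param path A `crw_path` from [simulate_path()].
#' @param initial_bearing Bearing the first step turned from.
#' @return Numeric vector of length `n_steps`.
#' @export
turning_angles <- function(path, initial_bearing) {
  h <- path$headings
  if (!length(h)) return(numeric(0))
  prev <- c(initial_bearing, h[-length(h)])
  d <- (h - prev) %% 360
  ifelse(d > 180, d - 360, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
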