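#' Experiment design: basins x step lengths x turning-angle SDs
#'
#' Defines a full factorial simulation grid. Each (basin, step length,
#' turn SD) cell gets `n_per_cell` independent paths; the per-cell seed is a
#' stable hash of the global seed with the cell labels, so adding or
#' reordering cells never perturbs other cells' draws.
#'
#' @param basins Named list of [lake_basin()] objects.
#' @param step_lengths Step lengths in meters.
#' @param turn_sds Turning-angle SDs in degrees.
#' @param n_per_cell Paths per cell (>= 1).
#' @param max_path_length Path cap in meters: a scalar applied everywhere or
#'   a named vector with one cap per basin.
#' @param swim_speed Swim speed used for passage-time conversion, m/s
#'   (default 0.17).
#' @param seed Global seed.
#' @param collision_coeff,collision_exponent Collision-inflation constants
#'   passed to [crw_params()].
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(basins, step_lengths, turn_sds, n_per_cell = 200L,
                              max_path_length = 75000, swim_speed = 0.17,
                              seed = 1L, collision_coeff = 0.1,
                              collision_exponent = 2) {
  stopifnot(length(basins) >= 1, !is.null(names(basins)),
            all(vapply(basins, inherits, logical(1), "lake_basin")),
            all(step_lengths > 0), all(turn_sds >= 0), n_per_cell >= 1,
            swim_speed > 0)
  caps <- if (length(max_path_length) == 1L) {
    stats::setNames(rep(max_path_length, length(basins)), names(basins))
  } else {
    if (!all(names(basins) %in% names(max_path_length)))
      stop("per-basin max_path_length must name every basin", call. = FALSE)
    max_path_length[names(basins)]
  }
  if (any(caps < max(step_lengths)))
    stop("every path cap must be at least the largest step length", call. = FALSE)
  structure(list(basins = basins, step_lengths = sort(step_lengths),
                 turn_sds = sort(turn_sds), n_per_cell = as.integer(n_per_cell),
                 caps = caps, swim_speed = swim_speed, seed = as.integer(seed),
                 collision_coeff = collision_coeff,
                 collision_exponent = collision_exponent),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d basin(s) x %d step length(s) x %d sigma(s), %d paths/cell (%d total)\n",
              length(x$basins), length(x$step_lengths), length(x$turn_sds),
              x$n_per_cell,
              length(x$basins) * length(x$step_lengths) * length(x$turn_sds) * x$n_per_cell))
  invisible(x)
}

#' Hypothetical-basin study design
#'
#' The four hypothetical basins crossed with step lengths
#' \{50, 75, 100, 150, 200\} m and turning-angle SDs \{2, 5, 15, 25\} degrees,
#' a 75 km path cap everywhere, and (by default) 200 paths per cell:
#' 80 cells, 16,000 paths.
#'
#' @param n_per_cell Paths per cell (200 full scale; use less for smoke runs).
#' @param seed Global seed.
#' @param basins Basin list (defaults to [make_hypothetical_basins()]).
#' @param ... Passed to [experiment_design()].
#' @return An `experiment_design`.
#' @export
hypothetical_design <- function(n_per_cell = 200L, seed = 1L,
                                basins = make_hypothetical_basins(), ...) {
  experiment_design(basins, step_lengths = c(50, 75, 100, 150, 200),
                    turn_sds = c(2, 5, 15, 25), n_per_cell = n_per_cell,
                    max_path_length = 75000, seed = seed, ...)
}

#' Real-lake study design
#'
#' The five real lakes (approximate shoreline fixtures) crossed with step
#' lengths \{50, 100, 200\} m and turning-angle SDs \{5, 15, 25\} degrees:
#' 45 cells, 1800 paths per lake at full scale. Path caps are lake-specific:
#' 75 km for Achonachie, Meig, and Lomond, 55.8 km for Garve, and 30.4 km for
#' Bassenthwaite.
#'
#' @inheritParams hypothetical_design
#' @param lakes Lake names to include (default all five).
#' @return An `experiment_design`.
#' @export
real_lakes_design <- function(n_per_cell = 200L, seed = 1L,
                              lakes = real_lake_table()$lake, ...) {
  tab <- real_lake_table()
  tab <- tab[match(lakes, tab$lake), ]
  basins <- lapply(tab$lake, load_real_lake_fixture)
  names(basins) <- tab$lake
  experiment_design(basins, step_lengths = c(50, 100, 200),
                    turn_sds = c(5, 15, 25), n_per_cell = n_per_cell,
                    max_path_length = stats::setNames(tab$cap_km * 1000, tab$lake),
                    seed = seed, ...)
}

# stable 32-bit string hash (djb2 mod a Mersenne prime) for per-cell seeds
seed_for_cell <- function(seed, basin, step_length, turn_sd) {
  s <- paste(seed, basin, format(step_length), format(turn_sd), sep = "|")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

#' Passage time from distance
#'
#' Converts a path distance to a lake passage time in days at a fixed swim
#' speed, assuming the fish swims continuously 24 h per day. At the default
#' 0.17 m/s a fish covers 14,688 m per day.
#'
#' @param distance Distance in meters (>= 0; vectorized).
#' @param swim_speed Swim speed in m/s (default 0.17).
#' @return Passage time in days.
#' @examples
#' passage_time(14688)  # 1 day
#' @export
passage_time <- function(distance, swim_speed = 0.17) {
  stopifnot(all(distance >= 0), swim_speed > 0)
  distance / (swim_speed * 86400)
}

#' Path cap from the longest observed successful migration
#'
#' The distance a fish swimming at `swim_speed` covers in the longest
#' successful passage time observed for a lake, constrained to `cap` meters.
#' (The shipped real-lake designs use the published per-lake caps directly;
#' this formula is exposed for sensitivity runs.)
#'
#' @param longest_success_days Longest successful passage time, days.
#' @param swim_speed Swim speed in m/s (default 0.17).
#' @param cap Upper bound in meters (default 75,000).
#' @return Path cap in meters.
#' @export
max_path_length_for_lake <- function(longest_success_days, swim_speed = 0.17,
                                     cap = 75000) {
  stopifnot(longest_success_days > 0, swim_speed > 0, cap > 0)
  pmin(longest_success_days * 86400 * swim_speed, cap)
}

#' Summarize one grid cell
#'
#' Collapses an ensemble into the cell metrics: success rate (percent of all
#' paths), and mean/SE of distance and passage time over successful paths
#' only (an all-failure cell reports success 0 with NA summaries, not an
#' error). `include_failures = TRUE` adds failures to the distance summaries
#' for sensitivity analysis.
#'
#' @param ens A `crw_ensemble` from [simulate_ensemble()].
#' @param swim_speed Swim speed, m/s.
#' @param include_failures Include failed paths in distance/passage summaries.
#' @return A one-row data.frame of cell metrics; the successful distances are
#'   attached as attribute `"distances"`.
#' @export
summarize_cell <- function(ens, swim_speed = 0.17, include_failures = FALSE) {
  stopifnot(inherits(ens, "crw_ensemble"))
  rec <- ens$records
  n <- nrow(rec)
  succ <- rec$outcome == "success"
  d <- rec$distance_m[if (include_failures) rep(TRUE, n) else succ]
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- data.frame(
    n_sims = n,
    n_success = sum(succ),
    success_rate = 100 * sum(succ) / n,
    n_failure_retries = sum(rec$outcome == "failure_retries"),
    mean_distance_m = if (length(d)) mean(d) else NA_real_,
    se_distance_m = se(d),
    mean_passage_days = if (length(d)) mean(passage_time(d, swim_speed)) else NA_real_,
    se_passage_days = se(passage_time(d, swim_speed)),
    mean_collisions = mean(rec$n_collisions)
  )
  attr(out, "distances") <- rec$distance_m[succ]
  out
}

#' Run a full simulation grid
#'
#' Simulates every cell of an [experiment_design()] and assembles the
#' per-cell summary table plus the long per-path record table. Deterministic:
#' the same design and seed give identical tables.
#'
#' @param design An `experiment_design`.
#' @param keep_paths Keep full trajectories for every path (memory-heavy;
#'   default FALSE).
#' @param progress Print one line per cell.
#' @return An object of class `lakewalk_grid`: `cells` (one row per cell) and
#'   `records` (one row per path, with `passage_days` filled for successes).
#' @export
run_grid <- function(design, keep_paths = FALSE, progress = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  cells <- list()
  records <- list()
  paths <- if (keep_paths) list() else NULL
  i <- 0L
  for (bn in names(design$basins)) {
    basin <- design$basins[[bn]]
    for (L in design$step_lengths) {
      for (sd in design$turn_sds) {
        i <- i + 1L
        params <- crw_params(step_length = L, turn_sd = sd,
                             max_path_length = design$caps[[bn]],
                             collision_coeff = design$collision_coeff,
                             collision_exponent = design$collision_exponent)
        cell_seed <- seed_for_cell(design$seed, bn, L, sd)
        ens <- tryCatch(
          simulate_ensemble(basin, params, n = design$n_per_cell,
                            seed = cell_seed, keep_points = keep_paths),
          error = function(e) stop(sprintf("cell (%s, L=%g, sigma=%g): %s",
                                           bn, L, sd, conditionMessage(e)),
                                   call. = FALSE))
        summ <- summarize_cell(ens, design$swim_speed)
        cells[[i]] <- cbind(data.frame(basin = bn, step_length = L,
                                       turn_sd = sd), summ)
        rec <- ens$records
        rec$basin <- bn
        rec$step_length <- L
        rec$turn_sd <- sd
        rec$success <- rec$outcome == "success"
        rec$passage_days <- ifelse(rec$success,
                                   passage_time(rec$distance_m, design$swim_speed),
                                   NA_real_)
        records[[i]] <- rec
        if (keep_paths) paths[[i]] <- ens$paths
        if (progress)
          message(sprintf("[%s L=%g sigma=%g] success %.1f%%", bn, L, sd,
                          summ$success_rate))
      }
    }
  }
  cells <- do.call(rbind, cells)
  records <- do.call(rbind, records)
  rownames(cells) <- rownames(records) <- NULL
  structure(list(cells = cells, records = records, paths = paths,
                 design = design), class = "lakewalk_grid")
}

#' @export
print.lakewalk_grid <- function(x, ...) {
  cat(sprintf("<lakewalk_grid> %d cells, %d paths, overall success %.1f%%\n",
              nrow(x$cells), nrow(x$records),
              100 * mean(x$records$success)))
  invisible(x)
}

#' Pooled success rate over a slice of the grid
#'
#' Pools per-path outcomes over any subset of basins, step lengths, and
#' turning-angle SDs (NULL means no restriction) and returns the percent
#' successful. This is the aggregation behind statements like "success at a
#' step length of 100 m, pooled over sigma".
#'
#' @param grid A `lakewalk_grid`.
#' @param basins,step_lengths,turn_sds Optional filters.
#' @return Percent of matching paths that succeeded.
#' @export
pooled_success_rate <- function(grid, basins = NULL, step_lengths = NULL,
                                turn_sds = NULL) {
  stopifnot(inherits(grid, "lakewalk_grid"))
  r <- grid$records
  keep <- rep(TRUE, nrow(r))
  if (!is.null(basins)) keep <- keep & r$basin %in% basins
  if (!is.null(step_lengths)) keep <- keep & r$step_length %in% step_lengths
  if (!is.null(turn_sds)) keep <- keep & r$turn_sd %in% turn_sds
  if (!any(keep)) stop("no paths match the requested slice", call. = FALSE)
  100 * mean(r$success[keep])
}

#' Mean successful-path distance over a slice of the grid
#'
#' @inheritParams pooled_success_rate
#' @return Mean distance (m) over successful matching paths.
#' @export
pooled_mean_distance <- function(grid, basins = NULL, step_lengths = NULL,
                                 turn_sds = NULL) {
  r <- grid$records
  keep <- r$success
  if (!is.null(basins)) keep <- keep & r$basin %in% basins
  if (!is.null(step_lengths)) keep <- keep & r$step_length %in% step_lengths
  if (!is.null(turn_sds)) keep <- keep & r$turn_sd %in% turn_sds
  if (!any(keep)) return(NA_real_)
  mean(r$distance_m[keep])
}
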