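test_that("collision_sigma follows the inflation rule and is monotone in k", {
  expect_equal(collision_sigma(5, 0), 5)
  expect_equal(collision_sigma(5, 1), 5.5)
  expect_equal(collision_sigma(5, 3), 9.5)
  expect_equal(collision_sigma(5, 0:3), c(5, 5.5, 7, 9.5))
  # alternative published reading, via the exposed constants
  expect_equal(collision_sigma(5, 2, coeff = 0.1, exponent = 1), 6)
  ks <- 0:50
  expect_true(all(diff(collision_sigma(2, ks)) >= 0))
  expect_error(collision_sigma(5, -1))
})

test_that("draw_turn sampling matches its nominal distribution", {
  expect_equal(draw_turn(100, sigma = 0, seed = 5), rep(0, 100))
  x5 <- draw_turn(1e5, sigma = 5, seed = 7)
  expect_lt(abs(stats::sd(x5) - 5) / 5, 0.02)
  x25 <- draw_turn(1e5, sigma = 25, seed = 8)
  expect_lt(abs(mean(x25)), 0.3)
  # reproducible, and distinct streams differ
  expect_identical(draw_turn(10, 5, seed = 1), draw_turn(10, 5, seed = 1))
  expect_false(identical(draw_turn(10, 5, seed = 1), draw_turn(10, 5, seed = 2)))
})

test_that("sigma = 0 in a clear corridor gives the analytic straight path", {
  basin <- short_corridor()
  p <- crw_params(step_length = 100, turn_sd = 0, max_path_length = 75000)
  path <- simulate_path(basin, p, seed = 3)
  expect_equal(as.character(path$outcome), "success")
  expect_equal(path$n_steps, 10L)
  expect_equal(path$distance, 1000)
  expect_equal(path$points[11, ], c(0, 1000))
  expect_equal(unique(path$headings), 0)
})

test_that("the path cap binds immediately when max_path_length = L", {
  # capture behind the start: one step away from it, then the cap binds
  poly <- polygon2d(rbind(c(-500, 0), c(500, 0), c(500, 5000), c(-500, 5000)))
  basin <- lake_basin("trap", poly, start = c(0, 0), initial_bearing = 0,
                      capture = capture_region(c(400, 0), 20))
  p <- crw_params(step_length = 100, turn_sd = 0, max_path_length = 100)
  path <- simulate_path(basin, p, seed = 1)
  expect_equal(as.character(path$outcome), "failure_cap")
  expect_equal(path$n_steps, 1L)
  expect_equal(path$distance, 100)
})

test_that("paths satisfy their structural invariants across the sigma sweep", {
  basin <- make_circular_basin()
  for (sd in c(2, 5, 15, 25)) {
    p <- crw_params(step_length = 100, turn_sd = sd, max_path_length = 75000)
    ens <- simulate_ensemble(basin, p, n = 50, seed = 100 + sd,
                             keep_points = TRUE)
    rec <- ens$records
    expect_equal(rec$distance_m, rec$n_steps * 100)
    expect_true(all(rec$n_steps <= 750L))
    for (i in seq_len(nrow(rec))) {
      pts <- ens$paths[[i]]
      expect_equal(nrow(pts), rec$n_steps[i] + 1L)
      # every vertex in the lake, except that a successful final step may
      # land past the shoreline inside the straddling capture disc
      body <- pts[-nrow(pts), , drop = FALSE]
      expect_true(all(point_in_polygon(body, basin$polygon, tol = 1e-6)))
      last <- pts[nrow(pts), ]
      if (rec$outcome[i] == "success") {
        seg_ok <- segment_crosses_region(pts[nrow(pts) - 1L, ], last,
                                         basin$capture)
        expect_true(seg_ok)
      } else {
        expect_true(point_in_polygon(last, basin$polygon, tol = 1e-6))
      }
    }
  }
})

test_that("turning-angle SD is recovered on a collision-free corridor run", {
  basin <- corridor_basin()
  for (sd in c(5, 15)) {
    p <- crw_params(step_length = 100, turn_sd = sd, max_path_length = 1e6)
    path <- simulate_path(basin, p, seed = 50 + sd)
    expect_equal(path$n_collisions, 0)
    expect_equal(path$n_steps, 10000L)
    turns <- turning_angles(path, basin$initial_bearing)
    expect_lt(abs(stats::sd(turns) - sd) / sd, 0.03)
    expect_lt(abs(mean(turns)), 3 * sd / sqrt(1e4) * 3)
  }
})

test_that("ensembles are deterministic and substream-consistent", {
  basin <- make_circular_basin()
  p <- crw_params(step_length = 100, turn_sd = 15, max_path_length = 75000)
  e1 <- simulate_ensemble(basin, p, n = 200, seed = 9)
  e2 <- simulate_ensemble(basin, p, n = 200, seed = 9)
  expect_identical(e1$records, e2$records)
  # n = 1 equals the ensemble's substream 0
  single <- simulate_ensemble(basin, p, n = 1, seed = 9)
  expect_identical(single$records$n_steps, e1$records$n_steps[1])
  # substream windows line up: path k of the ensemble = first_stream k
  shifted <- simulate_ensemble(basin, p, n = 1, seed = 9, first_stream = 4)
  expect_identical(shifted$records$n_steps, e1$records$n_steps[5])
  # different seeds give different but comparably successful ensembles
  e3 <- simulate_ensemble(basin, p, n = 200, seed = 10)
  expect_false(identical(e1$records$n_steps, e3$records$n_steps))
  p1 <- mean(e1$records$outcome == "success")
  p3 <- mean(e3$records$outcome == "success")
  expect_lt(abs(p1 - p3), 4 * sqrt(p1 * (1 - p1) / 200) + 1e-9)
})

test_that("collision retries inflate sigma and a retry ceiling is honored", {
  # a thin sliver with the walker headed straight at the near wall: sigma = 0
  # can never turn, so the retry ceiling must trigger failure_retries
  poly <- polygon2d(rbind(c(-1000, 0), c(1000, 0), c(1000, 50), c(-1000, 50)))
  basin <- lake_basin("sliver", poly, start = c(0, 0), initial_bearing = 0,
                      capture = capture_region(c(900, 0), 5))
  p0 <- crw_params(step_length = 100, turn_sd = 0, max_path_length = 10000,
                   max_collision_retries = 20)
  path0 <- simulate_path(basin, p0, seed = 2)
  expect_equal(as.character(path0$outcome), "failure_retries")
  # with sigma > 0 the inflation rule frees the walker
  p1 <- crw_params(step_length = 100, turn_sd = 5, max_path_length = 10000)
  path1 <- simulate_path(basin, p1, seed = 2)
  expect_gt(path1$n_collisions, 0)
  expect_true(as.character(path1$outcome) %in%
                c("success", "failure_cap", "failure_retries"))
})

test_that("simulation rejects a start outside the lake", {
  poly <- polygon2d(rbind(c(-500, 0), c(500, 0), c(500, 1000), c(-500, 1000)))
  basin <- lake_basin("bad", poly, start = c(0, 0), initial_bearing = 0,
                      capture = capture_region(c(0, 1000), 50))
  basin$start <- c(5000, 5000)  # corrupt after construction
  p <- crw_params(step_length = 100, turn_sd = 5, max_path_length = 1000)
  expect_error(simulate_ensemble(basin, p, n = 1, seed = 1), "outside")
})
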