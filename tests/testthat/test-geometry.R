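test_that("polygon2d validates rings and computes area", {
  sq <- polygon2d(rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5)))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)
  # orientation is normalized, closing vertex dropped
  sq2 <- polygon2d(rbind(c(-0.5, 0.5), c(0.5, 0.5), c(0.5, -0.5), c(-0.5, -0.5),
                         c(-0.5, 0.5)))
  expect_equal(polygon_area(sq2), 1)
  expect_error(polygon2d(rbind(c(0, 0), c(1, 1))), "3 vertices")
  # bow-tie self-intersection rejected
  expect_error(polygon2d(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersecting")
  # holes subtract area
  holed <- polygon2d(10 * rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)),
                     holes = list(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))))
  expect_equal(polygon_area(holed), 400 - 4)
})

test_that("point_in_polygon handles interior, exterior, boundary, and holes", {
  sq <- polygon2d(rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5)))
  expect_true(point_in_polygon(c(0, 0), sq))
  expect_false(point_in_polygon(c(10, 10), sq))
  # boundary counts as inside (closed polygon)
  expect_true(point_in_polygon(c(0.5, 0), sq))
  expect_true(point_in_polygon(c(0.5, 0.5), sq))
  holed <- polygon2d(10 * rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)),
                     holes = list(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))))
  expect_false(point_in_polygon(c(0, 0), holed))   # inside the hole
  expect_true(point_in_polygon(c(5, 5), holed))
  expect_true(point_in_polygon(c(1, 0), holed))    # hole boundary is lake
})

test_that("point_in_polygon agrees with a winding-number oracle on random cases", {
  set.seed(11)
  for (rep in 1:10) {
    ring <- random_star_polygon(12)
    poly <- polygon2d(ring)
    pts <- cbind(stats::runif(1000, -1.6, 1.6), stats::runif(1000, -1.6, 1.6))
    got <- point_in_polygon(pts, poly, tol = 0)
    want <- apply(pts, 1, winding_inside, ring = poly$outer)
    expect_identical(as.logical(got), as.logical(want))
  }
})

test_that("point_in_polygon agrees with pracma::inpolygon", {
  skip_if_not_installed("pracma")
  set.seed(4)
  ring <- random_star_polygon(20)
  poly <- polygon2d(ring)
  pts <- cbind(stats::runif(2000, -1.6, 1.6), stats::runif(2000, -1.6, 1.6))
  got <- point_in_polygon(pts, poly, tol = 0)
  want <- pracma::inpolygon(pts[, 1], pts[, 2],
                            poly$outer[, 1], poly$outer[, 2])
  expect_identical(as.logical(got), as.logical(want))
})

test_that("step_endpoint moves along the bearing and preserves distance", {
  expect_equal(step_endpoint(c(0, 0), 0, 100), c(0, 100))
  expect_equal(step_endpoint(c(0, 0), 90, 100), c(100, 0))
  expect_equal(step_endpoint(c(0, 0), 45, 100),
               c(70.7106781, 70.7106781), tolerance = 1e-7)
  set.seed(2)
  for (i in 1:200) {
    p <- stats::rnorm(2, 0, 1000)
    th <- stats::runif(1, -720, 720)
    L <- stats::runif(1, 1e-3, 1e4)
    q <- step_endpoint(p, th, L)
    expect_equal(sqrt(sum((q - p)^2)), L, tolerance = 1e-9)
  }
})

test_that("bearing normalization is idempotent and wraps to [0, 360)", {
  x <- c(-10, 0, 359.99, 360, 725, -360)
  n1 <- normalize_bearing(x)
  expect_true(all(n1 >= 0 & n1 < 360))
  expect_equal(normalize_bearing(n1), n1)
  expect_equal(normalize_bearing(-10), 350)
})

test_that("segment_crosses_region matches a dense sampling oracle", {
  reg <- capture_region(c(0, 0), 1)
  expect_true(segment_crosses_region(c(-5, 0), c(5, 0), reg))  # through center
  expect_false(segment_crosses_region(c(5, 5), c(6, 9), reg))  # far outside
  # entering counts even if the far endpoint exits again
  expect_true(segment_crosses_region(c(-5, 0.5), c(5, 0.5), reg))
  set.seed(33)
  n_checked <- 0
  while (n_checked < 400) {
    a <- stats::runif(2, -4, 4); b <- stats::runif(2, -4, 4)
    center <- stats::runif(2, -2, 2); r <- stats::runif(1, 0.2, 1.5)
    # skip grazing cases below the 1 cm sampling resolution of the oracle
    d_seg <- abs(lakewalk:::point_segment_distance(center, a, b) - r)
    if (d_seg < 0.02) next
    got <- segment_crosses_region(a, b, capture_region(center, r))
    want <- sampling_crosses(a, b, center, r)
    expect_identical(got, want)
    n_checked <- n_checked + 1
  }
})

test_that("size_capture_region solves the exposed-arc radius", {
  # on a long straight edge half the circle is exposed: r = target / pi
  big <- polygon2d(1e4 * rbind(c(-1, 0), c(1, 0), c(1, 1), c(-1, 1)))
  reg440 <- size_capture_region(big, c(0, 0), 440)
  expect_equal(reg440$radius, 440 / pi, tolerance = 0.01)
  reg31 <- size_capture_region(big, c(0, 0), 31)
  expect_equal(reg31$radius, 31 / pi, tolerance = 0.01)
  # achieved exposed arc within 1% of target
  expect_lt(abs(exposed_arc_length(big, reg440$center, reg440$radius) - 440) / 440,
            0.01)
  expect_error(size_capture_region(big, c(0, 0), 0), "exposed_perimeter")
  expect_error(size_capture_region(big, c(0, 5000), 100), "boundary")
})

test_that("size_capture_region is monotone in the exposed perimeter", {
  big <- polygon2d(1e4 * rbind(c(-1, 0), c(1, 0), c(1, 1), c(-1, 1)))
  targets <- c(20, 50, 150, 440, 1000)
  radii <- vapply(targets, function(p)
    size_capture_region(big, c(0, 0), p)$radius, numeric(1))
  expect_true(all(diff(radii) > 0))
})

test_that("distance_to_boundary and projection behave on a square", {
  sq <- polygon2d(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_equal(distance_to_boundary(sq, c(5, 5)), 5)
  expect_equal(distance_to_boundary(sq, c(5, 0)), 0)
  expect_equal(lakewalk:::project_to_boundary(sq, c(5, 4)), c(5, 0))
})
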