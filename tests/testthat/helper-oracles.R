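# Independent oracles and small fixture builders shared across tests.

# winding-number containment oracle: total subtended angle > pi  <=>  inside.
# Independent of the package's even-odd crossing implementation.
winding_inside <- function(p, ring) {
  v <- sweep(ring, 2, p)
  v2 <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  cross <- v[, 1] * v2[, 2] - v[, 2] * v2[, 1]
  dot <- rowSums(v * v2)
  abs(sum(atan2(cross, dot))) > pi
}

# random star-shaped simple polygon around the origin
random_star_polygon <- function(n = 12, r_min = 0.5, r_max = 1.5) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, r_max)
  cbind(r * cos(th), r * sin(th))
}

# dense point-sampling oracle for segment-disc intersection (1 cm steps)
sampling_crosses <- function(a, b, center, radius, step = 0.01) {
  len <- sqrt(sum((b - a)^2))
  t <- seq(0, 1, by = if (len > 0) step / len else 1)
  pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  min(sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)) <= radius
}

# chi-squared upper-tail probability by numerical integration of the density,
# independent of pchisq
chisq_tail_integrate <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, q, Inf, rel.tol = 1e-12)$value
}

# open arena for collision-free runs: a huge square with the start moved to
# its center after construction (a basin normally starts on the shoreline;
# for parameter-recovery runs the walk must never be able to reach a wall)
corridor_basin <- function(half_width = 2e6, capture_radius = 50) {
  ring <- rbind(c(-half_width, 0), c(half_width, 0),
                c(half_width, 2 * half_width), c(-half_width, 2 * half_width))
  poly <- polygon2d(ring)
  b <- lake_basin("corridor", poly,
                  start = c(0, 0), initial_bearing = 0,
                  capture = capture_region(c(0, 2 * half_width), capture_radius))
  b$start <- c(0, half_width)
  b
}

# short corridor with the capture dead ahead at 1 km
short_corridor <- function() {
  poly <- polygon2d(rbind(c(-500, 0), c(500, 0), c(500, 1000), c(-500, 1000)))
  lake_basin("short_corridor", poly, start = c(0, 0), initial_bearing = 0,
             capture = capture_region(c(0, 1000), 50))
}
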