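#' Planar polygon in meters
#'
#' Constructs a validated planar polygon from an outer vertex ring and
#' optional hole rings. All geometry in lakewalk is Cartesian, in meters;
#' there is no geographic CRS handling. The outer ring is stored
#' counter-clockwise (positive signed area), holes clockwise; rings are
#' implicitly closed (the first vertex is not repeated).
#'
#' @param outer Two-column numeric matrix (or data.frame) of vertices, in
#'   meters. At least 3 vertices; must not self-intersect.
#' @param holes Optional list of hole rings, same format.
#' @return An object of class `polygon2d` with elements `outer` and `holes`.
#' @examples
#' sq <- polygon2d(cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)))
#' polygon_area(sq)
#' @export
polygon2d <- function(outer, holes = NULL) {
  outer <- as_ring(outer)
  if (nrow(outer) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(outer))) stop("polygon vertices must be finite", call. = FALSE)
  if (!cpp_ring_is_simple(outer[, 1], outer[, 2]))
    stop("polygon outer ring is self-intersecting or degenerate", call. = FALSE)
  if (ring_signed_area(outer) < 0) outer <- outer[rev(seq_len(nrow(outer))), , drop = FALSE]
  if (!is.null(holes)) {
    holes <- lapply(holes, function(h) {
      h <- as_ring(h)
      if (nrow(h) < 3L || !cpp_ring_is_simple(h[, 1], h[, 2]))
        stop("invalid hole ring", call. = FALSE)
      if (ring_signed_area(h) > 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
      h
    })
  }
  structure(list(outer = outer, holes = holes), class = "polygon2d")
}

as_ring <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("a ring must have two coordinate columns", call. = FALSE)
  storage.mode(x) <- "double"
  n <- nrow(x)
  # drop an explicit closing vertex
  if (n > 1L && all(x[1L, ] == x[n, ])) x <- x[-n, , drop = FALSE]
  dimnames(x) <- NULL
  x
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area and perimeter
#'
#' Shoelace area (holes subtracted) and boundary length of a [polygon2d()].
#'
#' @param poly A `polygon2d`.
#' @return Area in square meters / perimeter in meters.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "polygon2d"))
  a <- ring_signed_area(poly$outer)
  for (h in poly$holes) a <- a + ring_signed_area(h)  # holes are CW (negative)
  a
}

#' @rdname polygon_area
#' @export
polygon_perimeter <- function(poly) {
  stopifnot(inherits(poly, "polygon2d"))
  per <- function(r) {
    d <- r - r[c(2:nrow(r), 1L), , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
  }
  sum(vapply(c(list(poly$outer), poly$holes), per, numeric(1)))
}

#' @export
print.polygon2d <- function(x, ...) {
  cat(sprintf("<polygon2d> %d vertices, %d hole(s), area %.4g km^2\n",
              nrow(x$outer), length(x$holes), polygon_area(x) / 1e6))
  invisible(x)
}

#' Point-in-polygon test
#'
#' Even-odd containment with the boundary counted as inside (closed polygon),
#' so exact boundary landings never "escape" the lake. Points inside a hole
#' are outside; points on a hole boundary count as inside the polygon.
#'
#' @param p A length-2 numeric point, or an n x 2 matrix of points (meters).
#' @param poly A [polygon2d()].
#' @param tol Distance (m) within which a point is treated as on the boundary.
#' @return Logical vector, one element per point.
#' @export
point_in_polygon <- function(p, poly, tol = 1e-9) {
  stopifnot(inherits(poly, "polygon2d"))
  p <- if (is.null(dim(p))) matrix(p, ncol = 2L) else as.matrix(p)
  inside <- cpp_points_in_ring(p[, 1], p[, 2], poly$outer[, 1], poly$outer[, 2],
                               tol, TRUE)
  for (h in poly$holes) {
    in_hole <- cpp_points_in_ring(p[, 1], p[, 2], h[, 1], h[, 2], tol, FALSE)
    inside <- inside & !in_hole
  }
  inside
}

#' Bearing normalization
#'
#' Bearings are degrees clockwise from grid north (+y), kept in \[0, 360).
#' Normalization is idempotent.
#'
#' @param bearing Numeric vector of bearings in degrees.
#' @return Bearings wrapped to \[0, 360).
#' @export
normalize_bearing <- function(bearing) bearing %% 360

#' Step endpoint along a bearing
#'
#' Moves a point a fixed distance along a bearing (degrees clockwise from
#' north): the fixed-vector migration step of the walk.
#'
#' @param p Length-2 numeric point (meters).
#' @param bearing Bearing in degrees clockwise from north.
#' @param L Step length in meters (> 0).
#' @return The endpoint, a length-2 numeric vector.
#' @examples
#' step_endpoint(c(0, 0), 90, 100)  # due east
#' @export
step_endpoint <- function(p, bearing, L) {
  stopifnot(length(p) == 2L, is.finite(p), L > 0)
  rad <- normalize_bearing(bearing) * pi / 180
  c(p[1] + L * sin(rad), p[2] + L * cos(rad))
}

#' Capture (endpoint) region at the lake outlet
#'
#' A circular region centered on the shoreline whose entry terminates a
#' simulated migration with success. The region is sized by its *exposed
#' perimeter*: the arc length of the circle lying inside the lake polygon
#' (the circle straddles the shoreline at the outlet).
#'
#' @param center Length-2 numeric point on the lake boundary (meters).
#' @param radius Circle radius in meters (> 0).
#' @param exposed_perimeter Target exposed arc length in meters.
#' @return An object of class `capture_region`.
#' @seealso [size_capture_region()] which solves `radius` from the exposed
#'   perimeter for a given lake.
#' @export
capture_region <- function(center, radius, exposed_perimeter = NA_real_) {
  stopifnot(length(center) == 2L, is.finite(center), is.numeric(radius),
            radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 exposed_perimeter = as.numeric(exposed_perimeter)),
            class = "capture_region")
}

#' @export
print.capture_region <- function(x, ...) {
  cat(sprintf("<capture_region> center (%.1f, %.1f), radius %.2f m, exposed %.1f m\n",
              x$center[1], x$center[2], x$radius, x$exposed_perimeter))
  invisible(x)
}

#' Does a segment cross a capture region?
#'
#' TRUE iff the segment a -> b intersects the region's disc; entering counts
#' even if the far endpoint exits again (a long step can sweep through the
#' outlet region without stopping inside it).
#'
#' @param a,b Length-2 numeric segment endpoints (meters).
#' @param region A [capture_region()].
#' @return Logical scalar.
#' @export
segment_crosses_region <- function(a, b, region) {
  stopifnot(inherits(region, "capture_region"),
            is.finite(a), is.finite(b), length(a) == 2L, length(b) == 2L)
  point_segment_distance(region$center, a, b) <= region$radius
}

point_segment_distance <- function(p, a, b) {
  d <- b - a
  l2 <- sum(d^2)
  t <- if (l2 > 0) sum((p - a) * d) / l2 else 0
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * d - p)^2))
}

#' Distance from a point to the polygon boundary
#'
#' @param poly A [polygon2d()].
#' @param p Length-2 numeric point.
#' @return Minimum distance (m) to any boundary edge.
#' @export
distance_to_boundary <- function(poly, p) {
  stopifnot(inherits(poly, "polygon2d"), length(p) == 2L)
  ring_dist <- function(r) {
    a <- r
    b <- r[c(2:nrow(r), 1L), , drop = FALSE]
    d <- b - a
    l2 <- rowSums(d^2)
    t <- ((p[1] - a[, 1]) * d[, 1] + (p[2] - a[, 2]) * d[, 2]) / pmax(l2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    min(sqrt((a[, 1] + t * d[, 1] - p[1])^2 + (a[, 2] + t * d[, 2] - p[2])^2))
  }
  min(vapply(c(list(poly$outer), poly$holes), ring_dist, numeric(1)))
}

# nearest point on the polygon boundary; used to snap analytically placed
# start/capture positions onto the discretized shoreline
project_to_boundary <- function(poly, p) {
  best <- NULL
  best_d <- Inf
  for (r in c(list(poly$outer), poly$holes)) {
    a <- r
    b <- r[c(2:nrow(r), 1L), , drop = FALSE]
    d <- b - a
    l2 <- pmax(rowSums(d^2), .Machine$double.eps)
    t <- ((p[1] - a[, 1]) * d[, 1] + (p[2] - a[, 2]) * d[, 2]) / l2
    t <- pmin(pmax(t, 0), 1)
    qx <- a[, 1] + t * d[, 1]
    qy <- a[, 2] + t * d[, 2]
    dist <- sqrt((qx - p[1])^2 + (qy - p[2])^2)
    i <- which.min(dist)
    if (dist[i] < best_d) {
      best_d <- dist[i]
      best <- c(qx[i], qy[i])
    }
  }
  best
}

#' Exposed arc length of a circle inside a lake polygon
#'
#' Measures the total arc length of the circle of radius `r` about `center`
#' that lies inside `poly`. The circle is sampled at `n_angles` points and
#' each inside/outside transition is refined by bisection, so the returned
#' length is accurate well below the 1% tolerance used for capture sizing.
#'
#' @param poly A [polygon2d()].
#' @param center Circle center (length-2 numeric, meters).
#' @param r Circle radius (m).
#' @param n_angles Number of initial sample angles.
#' @return Arc length in meters.
#' @export
exposed_arc_length <- function(poly, center, r, n_angles = 1024L) {
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  pts <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
  ins <- point_in_polygon(pts, poly, tol = 0)
  if (all(ins)) return(2 * pi * r)
  if (!any(ins)) return(0)
  dtheta <- 2 * pi / n_angles
  inside_measure <- 0
  at <- function(th) {
    point_in_polygon(c(center[1] + r * cos(th), center[2] + r * sin(th)),
                     poly, tol = 0)
  }
  nxt <- c(2:n_angles, 1L)
  for (i in seq_len(n_angles)) {
    j <- nxt[i]
    lo <- theta[i]
    hi <- theta[i] + dtheta
    if (ins[i] == ins[j]) {
      if (ins[i]) inside_measure <- inside_measure + dtheta
    } else {
      # bisect the crossing angle
      a <- lo; b <- hi; fa <- ins[i]
      for (it in 1:40) {
        m <- (a + b) / 2
        if (at(m) == fa) a <- m else b <- m
      }
      crossing <- (a + b) / 2
      inside_measure <- inside_measure +
        if (ins[i]) crossing - lo else hi - crossing
    }
  }
  inside_measure * r
}

#' Size a capture region from its exposed perimeter
#'
#' Solves (by bisection) for the circle radius whose arc inside the lake has
#' the requested exposed length. On a locally straight shoreline half the
#' circle is exposed, so the radius approaches `exposed_perimeter / pi`; on
#' curved shorelines the radius is found numerically.
#'
#' @param poly A [polygon2d()] lake.
#' @param center Point on the lake boundary (within 1 m).
#' @param exposed_perimeter Target exposed arc length (m, > 0).
#' @param tol Relative tolerance on the achieved exposed arc (default 0.5%,
#'   comfortably inside the 1% contract).
#' @return A [capture_region()] whose measured exposed arc is within `tol`
#'   of the target.
#' @export
size_capture_region <- function(poly, center, exposed_perimeter, tol = 0.005) {
  stopifnot(inherits(poly, "polygon2d"))
  if (!is.numeric(exposed_perimeter) || exposed_perimeter <= 0)
    stop("exposed_perimeter must be > 0", call. = FALSE)
  if (distance_to_boundary(poly, center) > 1)
    stop("capture center must lie on the lake boundary (within 1 m)", call. = FALSE)
  center <- project_to_boundary(poly, center)
  target <- exposed_perimeter
  f <- function(r) exposed_arc_length(poly, center, r)
  diam <- 2 * sqrt(max(rowSums(sweep(poly$outer, 2, colMeans(poly$outer))^2)))
  lo <- target / (4 * pi)
  hi <- target / pi
  while (f(hi) < target) {
    lo <- hi
    hi <- hi * 2
    if (hi > diam)
      stop("no feasible capture radius for this exposed perimeter", call. = FALSE)
  }
  while (f(lo) > target) lo <- lo / 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  achieved <- f(r)
  if (abs(achieved - target) / target > tol)
    stop(sprintf("capture sizing did not converge (achieved %.2f m vs target %.2f m)",
                 achieved, target), call. = FALSE)
  reg <- capture_region(center, r, exposed_perimeter)
  reg$exposed_measured <- achieved
  reg
}

# convexity check used to skip segment-boundary tests in the simulator
is_convex <- function(poly) {
  if (length(poly$holes)) return(FALSE)
  r <- poly$outer
  n <- nrow(r)
  a <- r[c(2:n, 1L), , drop = FALSE] - r
  b <- a[c(2:n, 1L), , drop = FALSE]
  cr <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  all(cr >= -1e-9 * max(abs(cr)))
}
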