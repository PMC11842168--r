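#' Lake basin: polygon, migration start, and outlet capture region
#'
#' Bundles everything the walk simulator needs about one lake: the shoreline
#' polygon, the start point (the afferent river mouth), the initial bearing
#' (the direction at which that river intercepts the lake), and the outlet
#' capture region.
#'
#' @param name Lake name.
#' @param polygon A [polygon2d()] shoreline.
#' @param start Length-2 numeric start point on the boundary (within 1 m).
#' @param initial_bearing Initial bearing, degrees clockwise from north.
#' @param capture A [capture_region()].
#' @param approximate Logical flag marking basins whose shoreline is an
#'   approximate (synthetic) reconstruction rather than a digitized outline.
#' @return An object of class `lake_basin` with derived fields `area_km2` and
#'   `start_end_distance_km` (straight-line start to capture-center distance).
#' @export
lake_basin <- function(name, polygon, start, initial_bearing, capture,
                       approximate = FALSE) {
  stopifnot(inherits(polygon, "polygon2d"), inherits(capture, "capture_region"),
            length(start) == 2L, is.finite(start))
  if (distance_to_boundary(polygon, start) > 1)
    stop("start point must lie on the lake boundary (within 1 m)", call. = FALSE)
  if (distance_to_boundary(polygon, capture$center) > 1)
    stop("capture center must lie on the lake boundary (within 1 m)", call. = FALSE)
  structure(list(
    name = as.character(name),
    polygon = polygon,
    start = as.numeric(start),
    initial_bearing = normalize_bearing(initial_bearing),
    capture = capture,
    approximate = isTRUE(approximate),
    area_km2 = polygon_area(polygon) / 1e6,
    start_end_distance_km = sqrt(sum((start - capture$center)^2)) / 1000
  ), class = "lake_basin")
}

#' @export
print.lake_basin <- function(x, ...) {
  cat(sprintf("<lake_basin> %s%s: area %.3g km^2, start-end %.2f km, capture exposed %.0f m\n",
              x$name, if (x$approximate) " (approximate shoreline)" else "",
              x$area_km2, x$start_end_distance_km, x$capture$exposed_perimeter))
  invisible(x)
}

# capture sizing: "exposed_arc" solves the radius so the arc inside the lake
# matches the target (default); "circumference" reads the target as the total
# circle circumference (r = P / 2 pi), the alternative published convention
build_capture <- function(poly, center, perimeter,
                          sizing = c("exposed_arc", "circumference")) {
  sizing <- match.arg(sizing)
  if (sizing == "exposed_arc") {
    size_capture_region(poly, center, perimeter)
  } else {
    capture_region(project_to_boundary(poly, center), perimeter / (2 * pi),
                   perimeter)
  }
}

# inward normal bearing at a boundary point of a star-shaped-about-centroid
# polygon: points from p toward the centroid projection, as degrees cw from N
inward_bearing <- function(poly, p) {
  ctr <- colMeans(poly$outer)
  v <- ctr - p
  normalize_bearing(atan2(v[1], v[2]) * 180 / pi)
}

#' Circular hypothetical basin
#'
#' A circular lake of the stated surface area with the migration start and
#' the outlet capture center on the circumference a fixed chord apart. The
#' polygon radius is chosen so the *polygon* area (not the ideal circle) hits
#' the target exactly; the initial bearing is the inward normal at the start.
#'
#' @param area_km2 Lake surface area (default 25.0).
#' @param separation_km Straight-line start to capture-center distance
#'   (default 5.5).
#' @param exposed_perimeter Capture region exposed arc length, m (default 440).
#' @param n_vertices Number of polygon vertices (>= 256).
#' @param capture_sizing `"exposed_arc"` (default: the target is the arc of
#'   the capture circle inside the lake) or `"circumference"` (the target is
#'   the full circle circumference, radius = target / 2 pi).
#' @return A [lake_basin()].
#' @export
make_circular_basin <- function(area_km2 = 25.0, separation_km = 5.5,
                                exposed_perimeter = 440, n_vertices = 256L,
                                capture_sizing = "exposed_arc") {
  stopifnot(n_vertices >= 256L)
  A <- area_km2 * 1e6
  n <- as.integer(n_vertices)
  # area of the inscribed regular n-gon: 0.5 n R^2 sin(2 pi / n)
  R <- sqrt(A / (0.5 * n * sin(2 * pi / n)))
  d <- separation_km * 1000
  if (d >= 2 * R) stop("separation exceeds lake diameter", call. = FALSE)
  # vertex angles include 180 degrees so the start is an exact vertex
  phi <- pi + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  poly <- polygon2d(cbind(R * cos(phi), R * sin(phi)))
  start <- c(-R, 0)
  delta <- 2 * asin(d / (2 * R))
  cap_center <- project_to_boundary(poly, c(R * cos(pi - delta), R * sin(pi - delta)))
  capture <- build_capture(poly, cap_center, exposed_perimeter, capture_sizing)
  lake_basin("circular", poly, start, inward_bearing(poly, start), capture)
}

#' Elliptical hypothetical basin
#'
#' An axis-aligned ellipse of the stated area. Start and capture are placed
#' at the same parametric (angular) coordinates as on the circular basin;
#' the capture position is then slid along the boundary so the start-capture
#' separation matches `separation_km` (the angular placement alone cannot on
#' an ellipse).
#'
#' @param area_km2 Lake surface area (default 22.1).
#' @param aspect Major:minor axis ratio (default 2, read from basin shape
#'   sketches; configurable for robustness checks).
#' @inheritParams make_circular_basin
#' @return A [lake_basin()].
#' @export
make_elliptical_basin <- function(area_km2 = 22.1, aspect = 2,
                                  separation_km = 5.5, exposed_perimeter = 440,
                                  n_vertices = 512L,
                                  capture_sizing = "exposed_arc") {
  A <- area_km2 * 1e6
  n <- as.integer(n_vertices)
  s_n <- 0.5 * n * sin(2 * pi / n)  # polygon area = a * b * s_n
  b <- sqrt(A / (aspect * s_n))
  a <- aspect * b
  phi <- pi + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  poly <- polygon2d(cbind(a * cos(phi), b * sin(phi)))
  start <- c(-a, 0)
  d <- separation_km * 1000
  # same parametric angle as the circle, then adjust along the boundary
  chord <- function(t) sqrt((a * cos(t) - start[1])^2 + (b * sin(t) - start[2])^2) - d
  if (chord(0) < 0)
    stop("separation infeasible for this ellipse aspect", call. = FALSE)
  t_c <- stats::uniroot(chord, c(0, pi), tol = 1e-12)$root
  cap_center <- project_to_boundary(poly, c(a * cos(t_c), b * sin(t_c)))
  capture <- build_capture(poly, cap_center, exposed_perimeter, capture_sizing)
  lake_basin("elliptical", poly, start, inward_bearing(poly, start), capture)
}

#' Rounded-rectangular hypothetical basin (lateral or terminal)
#'
#' A rounded rectangle whose corner radius defaults to half the short side,
#' so each short end is a semicircular cap (a stadium). Both variants share
#' the polygon; they differ only in start/end placement:
#' \describe{
#'   \item{lateral}{start and capture on one long side, `separation_km` apart
#'     (inflow and outflow perpendicular to the basin axis).}
#'   \item{terminal}{start and capture at the apexes of the two end caps,
#'     `terminal_separation_km` apart (inflow and outflow at the basin ends,
#'     the drainage pattern of glacial ribbon lakes).}
#' }
#' By default the outer length is fixed by the terminal separation and the
#' height then follows from the area, giving an aspect ratio of about 4.4:1.
#' Passing `aspect` overrides this (the terminal separation then becomes
#' whatever the geometry yields).
#'
#' @param variant `"lateral"` or `"terminal"`.
#' @param area_km2 Lake surface area (default 27.8).
#' @param terminal_separation_km End-to-end start/capture distance for the
#'   terminal variant (default 11.3); also fixes the basin length.
#' @param aspect Optional outer length:height ratio overriding the default
#'   length solution.
#' @inheritParams make_circular_basin
#' @param n_arc Vertices per semicircular end cap.
#' @return A [lake_basin()].
#' @export
make_rectangular_basin <- function(variant = c("lateral", "terminal"),
                                   area_km2 = 27.8, separation_km = 5.5,
                                   terminal_separation_km = 11.3,
                                   aspect = NULL, exposed_perimeter = 440,
                                   n_arc = 129L,
                                   capture_sizing = "exposed_arc") {
  variant <- match.arg(variant)
  A <- area_km2 * 1e6
  cc <- (4 - pi) / 4  # area deficit factor for corner radius = H/2
  if (is.null(aspect)) {
    W <- terminal_separation_km * 1000
    disc <- W^2 - 4 * cc * A
    if (disc < 0) stop("area too large for the requested basin length", call. = FALSE)
    H <- (W - sqrt(disc)) / (2 * cc)
  } else {
    # W = aspect * H: aspect*H^2 - cc*H^2 = A
    H <- sqrt(A / (aspect - cc))
    W <- aspect * H
  }
  if (W <= H) stop("basin length must exceed its height", call. = FALSE)
  r <- H / 2
  cx <- W / 2 - r  # end-cap centers at (+-cx, 0)
  th <- seq(-pi / 2, pi / 2, length.out = as.integer(n_arc))
  right_cap <- cbind(cx + r * cos(th), r * sin(th))
  left_cap <- cbind(-cx - r * cos(th), -r * sin(th))
  ring <- rbind(c(-cx, -r), right_cap[-1, , drop = FALSE],
                c(cx, r), left_cap[-1, , drop = FALSE])
  ring <- ring[!duplicated(round(ring, 9)), , drop = FALSE]
  poly0 <- polygon2d(ring)
  # uniform rescale so the discretized polygon hits the target area exactly
  s <- sqrt(A / polygon_area(poly0))
  poly <- polygon2d(poly0$outer * s)
  H <- H * s; W <- W * s; r <- r * s; cx <- cx * s
  if (variant == "lateral") {
    d <- separation_km * 1000
    if (d / 2 > cx)
      stop("lateral separation does not fit on the straight side", call. = FALSE)
    start <- c(-d / 2, -r)
    cap_center <- c(d / 2, -r)
    bearing <- 0  # inward normal of the bottom side: due north
    name <- "rectangular_lateral"
  } else {
    start <- project_to_boundary(poly, c(-W / 2, 0))
    cap_center <- project_to_boundary(poly, c(W / 2, 0))
    bearing <- 90  # inward normal at the left cap apex: due east
    name <- "rectangular_terminal"
  }
  capture <- build_capture(poly, cap_center, exposed_perimeter, capture_sizing)
  lake_basin(name, poly, start, bearing, capture)
}

#' The four hypothetical study basins
#'
#' Builds the circular, elliptical, lateral-rectangular, and
#' terminal-rectangular basins used throughout the hypothetical-basin
#' experiments. Per-shape default areas are 25.0, 22.1, and 27.8 km^2 (the
#' rectangle variants share a polygon); `common_area_km2` forces all four to
#' one area instead (e.g. 24.3), since the two conventions circulating for
#' these basins are mutually inconsistent.
#'
#' @param common_area_km2 Optional single area applied to every basin.
#' @param exposed_perimeter Capture exposed arc length, m (default 440).
#' @return Named list of four [lake_basin()] objects.
#' @export
make_hypothetical_basins <- function(common_area_km2 = NULL,
                                     exposed_perimeter = 440,
                                     capture_sizing = "exposed_arc") {
  a_circ <- if (is.null(common_area_km2)) 25.0 else common_area_km2
  a_ell <- if (is.null(common_area_km2)) 22.1 else common_area_km2
  a_rect <- if (is.null(common_area_km2)) 27.8 else common_area_km2
  basins <- list(
    circular = make_circular_basin(a_circ, exposed_perimeter = exposed_perimeter,
                                   capture_sizing = capture_sizing),
    elliptical = make_elliptical_basin(a_ell, exposed_perimeter = exposed_perimeter,
                                       capture_sizing = capture_sizing),
    rectangular_lateral = make_rectangular_basin("lateral", a_rect,
                                                 exposed_perimeter = exposed_perimeter,
                                                 capture_sizing = capture_sizing),
    rectangular_terminal = make_rectangular_basin("terminal", a_rect,
                                                  exposed_perimeter = exposed_perimeter,
                                                  capture_sizing = capture_sizing)
  )
  basins
}
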