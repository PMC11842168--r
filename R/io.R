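#' Write / read a lake basin as GeoJSON
#'
#' Serializes a basin as a GeoJSON FeatureCollection in planar meter
#' coordinates: one Polygon feature (role `"lake"`) and two Point features
#' (roles `"start"` and `"capture_center"`, the latter carrying the capture
#' radius and exposed perimeter). Coordinates are written at full double
#' precision, so a write/read round trip reproduces the vertices exactly.
#'
#' @param basin A [lake_basin()].
#' @param path Output file path.
#' @return `write_basin_geojson` returns `path` invisibly;
#'   `read_basin_geojson` returns a [lake_basin()] (or, with
#'   `build_capture = FALSE`, a bare list of parts for callers that size the
#'   capture region themselves).
#' @export
write_basin_geojson <- function(basin, path) {
  stopifnot(inherits(basin, "lake_basin"))
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  rings <- c(list(close_ring(basin$polygon$outer)),
             lapply(basin$polygon$holes %||% list(), close_ring))
  fc <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(role = "lake", name = basin$name,
                             approximate = basin$approximate,
                             area_km2 = basin$area_km2),
           geometry = list(type = "Polygon",
                           coordinates = lapply(rings, function(r)
                             lapply(seq_len(nrow(r)), function(i) r[i, ])))),
      list(type = "Feature",
           properties = list(role = "start",
                             initial_bearing = basin$initial_bearing),
           geometry = list(type = "Point", coordinates = basin$start)),
      list(type = "Feature",
           properties = list(role = "capture_center",
                             radius = basin$capture$radius,
                             exposed_perimeter = basin$capture$exposed_perimeter),
           geometry = list(type = "Point", coordinates = basin$capture$center))
    )
  )
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' @rdname write_basin_geojson
#' @param build_capture Re-solve the capture radius from the stored exposed
#'   perimeter (TRUE) or return the raw parts (FALSE).
#' @export
read_basin_geojson <- function(path, build_capture = TRUE) {
  fc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  feats <- fc$features
  roles <- vapply(feats$properties$role, identity, character(1))
  lake_i <- which(roles == "lake")
  start_i <- which(roles == "start")
  cap_i <- which(roles == "capture_center")
  if (!length(lake_i) || !length(start_i) || !length(cap_i))
    stop("GeoJSON must contain lake, start, and capture_center features",
         call. = FALSE)
  coords <- feats$geometry$coordinates[[lake_i]]
  # jsonlite parses Polygon coordinates as an [n_rings, n_pts, 2] array when
  # ring lengths agree, or as a list of per-ring matrices otherwise
  rings <- if (is.array(coords) && length(dim(coords)) == 3) {
    lapply(seq_len(dim(coords)[1]), function(i) coords[i, , ])
  } else if (is.list(coords)) {
    lapply(coords, as.matrix)
  } else {
    list(as.matrix(coords))
  }
  rings <- lapply(rings, as_ring)
  poly <- polygon2d(rings[[1]], holes = if (length(rings) > 1) rings[-1])
  start <- as.numeric(feats$geometry$coordinates[[start_i]])
  cap_center <- as.numeric(feats$geometry$coordinates[[cap_i]])
  bearing <- feats$properties$initial_bearing[[start_i]]
  exposed <- feats$properties$exposed_perimeter[[cap_i]]
  name <- feats$properties$name[[lake_i]]
  approx <- isTRUE(feats$properties$approximate[[lake_i]])
  if (!build_capture) {
    return(list(polygon = poly, start = start, capture_center = cap_center,
                initial_bearing = bearing, exposed_perimeter = exposed,
                name = name, approximate = approx,
                radius = feats$properties$radius[[cap_i]]))
  }
  capture <- size_capture_region(poly, cap_center, exposed)
  lake_basin(name, poly, start, bearing, capture, approximate = approx)
}

#' Polygon to/from WKT
#'
#' Minimal WKT support for planar polygons (`POLYGON ((...), (...))`, outer
#' ring first, then holes), for interchange with GIS tooling.
#'
#' @param poly A [polygon2d()].
#' @param wkt A WKT `POLYGON` string.
#' @return A WKT string / a [polygon2d()].
#' @export
polygon_to_wkt <- function(poly) {
  stopifnot(inherits(poly, "polygon2d"))
  fmt_ring <- function(r) {
    r <- rbind(r, r[1, , drop = FALSE])
    paste0("(", paste(sprintf("%.10g %.10g", r[, 1], r[, 2]), collapse = ", "), ")")
  }
  rings <- c(list(poly$outer), poly$holes %||% list())
  paste0("POLYGON (", paste(vapply(rings, fmt_ring, character(1)),
                            collapse = ", "), ")")
}

#' @rdname polygon_to_wkt
#' @export
polygon_from_wkt <- function(wkt) {
  stopifnot(is.character(wkt), length(wkt) == 1L)
  body <- sub("(?i)^\\s*POLYGON\\s*\\(", "", wkt, perl = TRUE)
  if (identical(body, wkt)) stop("not a WKT POLYGON string", call. = FALSE)
  body <- sub("\\)\\s*$", "", body)
  ring_strs <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1]]
  if (!length(ring_strs)) stop("no rings found in WKT", call. = FALSE)
  rings <- lapply(ring_strs, function(s) {
    s <- gsub("[()]", "", s)
    pts <- strsplit(trimws(strsplit(s, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
    as_ring(m)
  })
  polygon2d(rings[[1]], holes = if (length(rings) > 1) rings[-1])
}

#' Write grid results as tidy CSVs with a run manifest
#'
#' Writes `cells.csv` (one row per grid cell) and `paths.csv` (one row per
#' simulated path), plus `manifest.json` recording the seed, the design
#' parameters, MD5 checksums of the written files, and the package version,
#' so any output CSV is traceable to the configuration that produced it.
#'
#' @param grid A `lakewalk_grid` from [run_grid()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_grid_csv <- function(grid, dir) {
  stopifnot(inherits(grid, "lakewalk_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells_path <- file.path(dir, "cells.csv")
  paths_path <- file.path(dir, "paths.csv")
  utils::write.csv(grid$cells, cells_path, row.names = FALSE)
  rec <- grid$records[, c("basin", "step_length", "turn_sd", "path_id",
                          "outcome", "n_steps", "distance_m", "passage_days",
                          "n_collisions")]
  utils::write.csv(rec, paths_path, row.names = FALSE)
  design <- grid$design
  manifest <- list(
    package = "lakewalk",
    version = as.character(utils::packageVersion("lakewalk")),
    seed = design$seed,
    n_per_cell = design$n_per_cell,
    step_lengths = design$step_lengths,
    turn_sds = design$turn_sds,
    basins = names(design$basins),
    caps_m = as.list(design$caps),
    swim_speed = design$swim_speed,
    collision_coeff = design$collision_coeff,
    collision_exponent = design$collision_exponent,
    checksums = list(
      cells.csv = unname(tools::md5sum(cells_path)),
      paths.csv = unname(tools::md5sum(paths_path))
    )
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Trajectories as GeoJSON LineStrings
#'
#' Writes the kept trajectories of an ensemble as a GeoJSON
#' FeatureCollection of LineString features with per-path properties.
#'
#' @param ens A `crw_ensemble` simulated with `keep_points = TRUE`.
#' @param path Output file path.
#' @export
write_paths_geojson <- function(ens, path) {
  stopifnot(inherits(ens, "crw_ensemble"))
  if (is.null(ens$paths))
    stop("ensemble was simulated without keep_points = TRUE", call. = FALSE)
  feats <- lapply(seq_along(ens$paths), function(i) {
    m <- ens$paths[[i]]
    rec <- ens$records[i, ]
    list(type = "Feature",
         properties = list(path_id = rec$path_id,
                           outcome = as.character(rec$outcome),
                           n_steps = rec$n_steps,
                           distance_m = rec$distance_m),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(j) m[j, ])))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}
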