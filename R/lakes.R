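#' Reference table for the five real study lakes
#'
#' Published per-lake constants used by the real-lake simulations and the
#' telemetry comparisons: surface area, outlet capture exposed perimeter,
#' simulation path cap, longest successful passage observed, and the
#' empirical migration summaries (telemetry success rate and passage
#' mean/SD with the number of tracked fish).
#'
#' @return A data.frame with one row per lake.
#' @export
real_lake_table <- function() {
  data.frame(
    lake = c("Achonachie", "Meig", "Garve", "Lomond", "Bassenthwaite"),
    area_km2 = c(0.69, 0.45, 1.83, 71, 5.1),
    exposed_perimeter_m = c(31, 29, 50, 200, 73),
    cap_km = c(75, 75, 55.8, 75, 30.4),
    longest_success_days = c(34.32, 31.71, 30.21, 21.79, 5.58),
    empirical_success_pct = c(31, 35, 55, 21, 46),
    n_fish = c(5, 6, 12, 28, 15),
    passage_mean_days = c(19.6, 14.9, 1.5, 5.2, 2.2),
    passage_sd_days = c(7.6, 17.5, 1.4, 4.2, 1.4)
  )
}

#' Load an approximate real-lake basin fixture
#'
#' Reads one of the five bundled shoreline fixtures and returns it as a
#' [lake_basin()]. The fixtures are *synthetic approximations* of the real
#' shorelines (smooth harmonic outlines with roughly the right elongation and
#' start/outlet placement; they are not digitized maps) and are flagged
#' `approximate = TRUE`. On load the polygon is rescaled so its area matches
#' the published surface area exactly, and the outlet capture region is sized
#' to the lake's published exposed perimeter.
#'
#' @param name One of `"Achonachie"`, `"Meig"`, `"Garve"`, `"Lomond"`,
#'   `"Bassenthwaite"`.
#' @return A [lake_basin()] with `approximate = TRUE`.
#' @export
load_real_lake_fixture <- function(name) {
  tab <- real_lake_table()
  if (!name %in% tab$lake)
    stop(sprintf("unknown lake '%s'; known: %s", name,
                 paste(tab$lake, collapse = ", ")), call. = FALSE)
  row <- tab[tab$lake == name, ]
  path <- system.file("extdata", "lakes", paste0(tolower(name), ".geojson"),
                      package = "lakewalk", mustWork = TRUE)
  raw <- read_basin_geojson(path, build_capture = FALSE)
  s <- sqrt(row$area_km2 * 1e6 / polygon_area(raw$polygon))
  poly <- polygon2d(raw$polygon$outer * s,
                    holes = lapply(raw$polygon$holes %||% list(),
                                   function(h) h * s))
  start <- project_to_boundary(poly, raw$start * s)
  cap_center <- project_to_boundary(poly, raw$capture_center * s)
  capture <- size_capture_region(poly, cap_center, row$exposed_perimeter_m)
  lake_basin(name, poly, start, raw$initial_bearing, capture,
             approximate = TRUE)
}
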