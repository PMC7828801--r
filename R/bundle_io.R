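#' Write a study bundle to a directory of plain-text files
#'
#' Serialises a bundle as `areas.csv`, `adjacency.gal` (GAL neighbour
#' list), `population.csv`, `exposure.csv`, `deaths.csv`,
#' `deaths_strata.csv`, `areas.geojson` (square cell polygons), a
#' `truth.json` block for synthetic bundles, and a `manifest.json` with
#' md5 checksums and schema metadata.
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(bundle$lattice$areas, p("areas.csv"), progress = FALSE)
  write_gal(bundle$lattice, p("adjacency.gal"))
  readr::write_csv(bundle$population, p("population.csv"), progress = FALSE)
  readr::write_csv(bundle$exposure, p("exposure.csv"), progress = FALSE)
  readr::write_csv(bundle$deaths, p("deaths.csv"), progress = FALSE)
  readr::write_csv(bundle$deaths_strata, p("deaths_strata.csv"), progress = FALSE)
  write_geojson(bundle$lattice, p("areas.geojson"))
  truth <- bundle$truth
  if (!is.null(bundle$risk_profile)) truth$risk_profile <- bundle$risk_profile
  if (!is.null(truth)) {
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  files <- c("areas.csv", "adjacency.gal", "population.csv", "exposure.csv",
             "deaths.csv", "deaths_strata.csv", "areas.geojson",
             if (!is.null(truth)) "truth.json")
  manifest <- list(
    schema_version = "1.0",
    n_areas = bundle$lattice$n_areas,
    years = bundle$years,
    seed = bundle$truth$seed,
    files = as.list(setNames(unname(tools::md5sum(file.path(dir, files))), files))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load and validate a study bundle from disk
#'
#' Reads the files written by [write_bundle()], type-coerces all tables,
#' and validates the schema: consistent area and year sets across tables,
#' symmetric adjacency (asymmetric neighbour lists are rejected, not
#' repaired), nonnegative counts, positive populations, and deaths not
#' exceeding population.
#'
#' @param dir bundle directory.
#' @return a `study_bundle`.
#' @export
load_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("areas.csv", "adjacency.gal", "population.csv",
              "exposure.csv", "deaths.csv")) {
    assert_that_(file.exists(p(f)), sprintf("bundle is missing `%s`", f))
  }
  rd <- function(f, types) readr::read_csv(p(f), col_types = types, progress = FALSE)
  areas <- rd("areas.csv", readr::cols(
    area_id = "i", subarea = "c", degurba = "c", row = "i", col = "i",
    x = "d", y = "d"))
  edges <- read_gal(p("adjacency.gal"))
  lattice <- structure(
    list(areas = areas, edges = edges, n_areas = nrow(areas),
         nr = max(areas$row), nc = max(areas$col)),
    class = "area_lattice"
  )
  population <- rd("population.csv", readr::cols(
    area_id = "i", year = "i", gender = "c", age_class = "i", count = "i"))
  exposure <- rd("exposure.csv", readr::cols(area_id = "i", year = "i", pm25 = "d"))
  assert_that_(all(exposure$pm25 > 0), "exposure values must be positive")
  deaths <- rd("deaths.csv", readr::cols(area_id = "i", year = "i", deaths = "i"))
  deaths_strata <- if (file.exists(p("deaths_strata.csv"))) {
    rd("deaths_strata.csv", readr::cols(
      area_id = "i", year = "i", gender = "c", age_class = "i", deaths = "i"))
  } else NULL
  truth <- if (file.exists(p("truth.json"))) {
    tr <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    if (!is.null(tr$true_rr)) tr$true_rr <- as_tibble(tr$true_rr)
    tr
  } else NULL
  risk_profile <- if (!is.null(truth$risk_profile)) as_tibble(truth$risk_profile) else NULL
  years <- sort(unique(deaths$year))
  new_study_bundle(lattice, population, exposure, deaths, deaths_strata,
                   years, truth, risk_profile)
}

# square cell polygons so bundles are mappable without a GIS stack
write_geojson <- function(lattice, path) {
  features <- purrr::pmap(lattice$areas, function(area_id, subarea, degurba,
                                                  row, col, ...) {
    y0 <- lattice$nr - row + 1
    ring <- list(c(col - 0.5, y0 - 0.5), c(col + 0.5, y0 - 0.5),
                 c(col + 0.5, y0 + 0.5), c(col - 0.5, y0 + 0.5),
                 c(col - 0.5, y0 - 0.5))
    list(type = "Feature",
         properties = list(area_id = area_id, subarea = subarea,
                           degurba = degurba),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}
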