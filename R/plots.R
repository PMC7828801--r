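#' @importFrom ggplot2 ggplot aes geom_tile geom_point facet_wrap
#'   scale_fill_manual scale_fill_viridis_c labs theme_minimal autoplot
#'   ggsave coord_equal geom_pointrange geom_hline
#' @export
ggplot2::autoplot

rr_bin_labels <- c("< 0.75", "0.75 - 1.00", "1.00 - 1.25", "> 1.25")
pp_bin_labels <- c("< 0.10", "0.10 - 0.90", "> 0.90")

bin_values <- function(values, scheme) {
  if (scheme == "rr_bins") {
    cut(values, c(-Inf, 0.75, 1, 1.25, Inf), labels = rr_bin_labels)
  } else {
    cut(values, c(-Inf, 0.10, 0.90, Inf), labels = pp_bin_labels)
  }
}

choropleth_data <- function(values, lattice) {
  meta <- lattice$areas
  if (!all(c("row", "col") %in% names(meta))) {
    warning("lattice has no grid coordinates; falling back to point layout")
    meta$col <- meta$x; meta$row <- -meta$y
  }
  values |>
    inner_join(meta[, c("area_id", "row", "col")], by = "area_id") |>
    mutate(px = .data$col, py = max(meta$row) - .data$row + 1)
}

#' Choropleth of a per-area risk summary
#'
#' Tile map of the lattice, faceted by year, binned with the conventional
#' relative-risk cut points (0.75 / 1.00 / 1.25) or exceedance-probability
#' cut points (0.10 / 0.90).
#'
#' @param object a `dm_risk` tibble from [summarize_rr()].
#' @param lattice the `area_lattice` the summary refers to.
#' @param scheme `"rr_bins"` (bin `rr_median`) or `"pp_bins"` (bin `pp`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dm_risk <- function(object, lattice, scheme = c("rr_bins", "pp_bins"),
                             ...) {
  scheme <- match.arg(scheme)
  value_col <- if (scheme == "rr_bins") "rr_median" else "pp"
  df <- choropleth_data(object, lattice) |>
    mutate(bin = bin_values(.data[[value_col]], scheme))
  pal <- if (scheme == "rr_bins") {
    setNames(c("#2166ac", "#d1e5f0", "#fddbc7", "#b2182b"), rr_bin_labels)
  } else {
    setNames(c("#2166ac", "#f7f7f7", "#b2182b"), pp_bin_labels)
  }
  ggplot(df, aes(x = .data$px, y = .data$py, fill = .data$bin)) +
    geom_tile(colour = "grey40", linewidth = 0.1) +
    scale_fill_manual(values = pal, drop = FALSE,
                      name = if (scheme == "rr_bins") "RR (median)" else "PP(RR > 1)") +
    facet_wrap(~year) +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Posterior coefficient intervals of a fit
#'
#' @param object a `dm_fit`.
#' @param ... passed to [tidy.dm_fit()].
#' @return a ggplot object.
#' @export
autoplot.dm_fit <- function(object, ...) {
  td <- tidy(object, ...)
  ggplot(td, aes(x = .data$term, y = .data$estimate,
                 ymin = .data$conf.low, ymax = .data$conf.high)) +
    geom_pointrange() +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    labs(x = NULL, y = "posterior mean (95% CrI), log scale",
         title = object$spec$grid_id) +
    theme_minimal()
}

#' Render per-year choropleth files
#'
#' Writes one PNG map per year plus one geo-annotated GeoJSON per year
#' (cell polygons carrying the mapped value, bin, and class), so results
#' remain inspectable without the plotting stack.
#'
#' @param values a `dm_risk` tibble (or any tibble with `area_id`, `year`
#'   and the mapped value column).
#' @param lattice the `area_lattice`.
#' @param scheme `"rr_bins"` or `"pp_bins"`.
#' @param dir output directory.
#' @param width,height device size in inches.
#' @return tibble `year`, `png`, `geojson` of written paths.
#' @export
render_choropleth <- function(values, lattice, scheme = c("rr_bins", "pp_bins"),
                              dir = ".", width = 6, height = 5) {
  scheme <- match.arg(scheme)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  value_col <- if (scheme == "rr_bins") "rr_median" else "pp"
  out <- purrr::map(sort(unique(values$year)), function(yr) {
    sub <- values[values$year == yr, ]
    class(sub) <- class(values)
    g <- autoplot.dm_risk(sub, lattice, scheme = scheme)
    png_path <- file.path(dir, sprintf("map_%s_%d.png", scheme, yr))
    ggsave(png_path, g, width = width, height = height, dpi = 120)
    gj_path <- file.path(dir, sprintf("map_%s_%d.geojson", scheme, yr))
    annotated_geojson(sub, lattice, value_col, scheme, gj_path)
    tibble(year = yr, png = png_path, geojson = gj_path)
  })
  bind_rows(out)
}

annotated_geojson <- function(values, lattice, value_col, scheme, path) {
  vals <- values
  vals$bin <- as.character(bin_values(vals[[value_col]], scheme))
  lut <- split(vals, vals$area_id)
  features <- purrr::pmap(lattice$areas, function(area_id, subarea, degurba,
                                                  row, col, ...) {
    y0 <- lattice$nr - row + 1
    ring <- list(c(col - 0.5, y0 - 0.5), c(col + 0.5, y0 - 0.5),
                 c(col + 0.5, y0 + 0.5), c(col - 0.5, y0 + 0.5),
                 c(col - 0.5, y0 - 0.5))
    rec <- lut[[as.character(area_id)]]
    props <- list(area_id = area_id, subarea = subarea, degurba = degurba)
    if (!is.null(rec)) {
      props$value <- rec[[value_col]][1]
      props$bin <- rec$bin[1]
      if ("class" %in% names(rec)) props$class <- rec$class[1]
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}
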