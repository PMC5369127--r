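# Plain-text readers/writers. Rasters travel as CSV(x, y, value) holding the
# valid cells only, plus a JSON sidecar with the grid geometry and mask-free
# metadata; vectors travel as GeoJSON (polygons, points) or CSV (points).
# CSV dialect is fixed: comma separator, "." decimal, UTF-8, header row.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a raster field as CSV with a JSON sidecar
#'
#' The CSV holds one row per valid cell (`x`, `y`, `value`, cell centres);
#' nodata cells are absent. The sidecar `<path>.json` records the grid
#' geometry, units and layer name so the round trip reproduces values, mask
#' and geometry (values to better than 1e-12).
#'
#' @param field A `raster_field`.
#' @param path CSV file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns the
#'   reconstructed `raster_field`.
#' @export
write_raster <- function(field, path) {
  stopifnot(inherits(field, "raster_field"))
  g <- attr(field, "grid")
  ok <- !is.na(field$value)
  lines <- c(
    "x,y,value",
    paste(fmt_num(field$x[ok]), fmt_num(field$y[ok]), fmt_num(field$value[ok]),
      sep = ","
    )
  )
  writeLines(lines, path)
  jsonlite::write_json(
    list(
      x0 = g$x0, y0 = g$y0, cell_size = g$cell_size,
      n_rows = g$n_rows, n_cols = g$n_cols,
      units = attr(field, "units"), name = attr(field, "layer_name")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) abort(paste0("raster file not found: ", path))
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) abort(paste0("raster sidecar not found: ", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  grid <- structure(
    list(
      x0 = meta$x0, y0 = meta$y0, cell_size = meta$cell_size,
      n_rows = as.integer(meta$n_rows), n_cols = as.integer(meta$n_cols)
    ),
    class = "referent_grid"
  )
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "value") %in% names(df))) {
    abort(paste0("malformed raster CSV (need x,y,value): ", path))
  }
  s <- grid$cell_size
  j <- 1L + floor((df$x - grid$x0) / s)
  i <- 1L + floor((grid$y0 - df$y) / s)
  if (any(i < 1 | i > grid$n_rows | j < 1 | j > grid$n_cols)) {
    abort(paste0("raster CSV contains points outside the sidecar grid: ", path))
  }
  v <- rep(NA_real_, grid_n_cells(grid))
  v[(i - 1L) * grid$n_cols + j] <- df$value
  raster_field(grid, v, units = meta$units %||% "", name = meta$name %||% "")
}

ring_to_geojson_coords <- function(ring) {
  closed <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

#' Write / read zone maps and site sets as GeoJSON or CSV
#'
#' Zone maps are written as a GeoJSON FeatureCollection of polygons with
#' `zone_id` and `value` properties; site sets as GeoJSON points or, for
#' `.csv` paths, as a two-column `x,y` CSV. Geometry and attributes
#' round-trip exactly; invalid (self-intersecting) polygons raise an error
#' naming the offending feature ids.
#'
#' @param x A `zone_map` or `site_set`.
#' @param path Output path (`.geojson`/`.json`, or `.csv` for sites).
#' @export
write_vector <- function(x, path) {
  if (inherits(x, "zone_map")) {
    features <- purrr::map(seq_len(nrow(x)), function(k) {
      list(
        type = "Feature",
        properties = list(zone_id = x$zone_id[k], value = x$value[k]),
        geometry = list(
          type = "Polygon",
          coordinates = list(ring_to_geojson_coords(x$geometry[[k]]))
        )
      )
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", features = features),
      path,
      auto_unbox = TRUE, digits = NA
    )
  } else if (inherits(x, "site_set") || is.data.frame(x)) {
    if (grepl("\\.csv$", path)) {
      writeLines(c("x,y", paste(fmt_num(x$x), fmt_num(x$y), sep = ",")), path)
    } else {
      features <- purrr::map(seq_len(nrow(x)), function(k) {
        list(
          type = "Feature", properties = list(id = k),
          geometry = list(type = "Point", coordinates = c(x$x[k], x$y[k]))
        )
      })
      jsonlite::write_json(
        list(type = "FeatureCollection", features = features),
        path,
        auto_unbox = TRUE, digits = NA
      )
    }
  } else {
    abort("`x` must be a zone_map or site_set.")
  }
  invisible(path)
}

#' @rdname write_vector
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) abort(paste0("vector file not found: ", path))
  if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(df))) {
      abort(paste0("malformed point CSV (need x,y headers): ", path))
    }
    return(site_set(df))
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    abort(paste0("not a GeoJSON FeatureCollection: ", path))
  }
  types <- purrr::map_chr(gj$features, ~ .x$geometry$type)
  if (all(types == "Point")) {
    xy <- purrr::map(gj$features, ~ unlist(.x$geometry$coordinates))
    return(site_set(
      purrr::map_dbl(xy, 1), purrr::map_dbl(xy, 2)
    ))
  }
  if (!all(types == "Polygon")) abort("mixed or unsupported GeoJSON geometry types.")
  ids <- purrr::map_chr(gj$features, ~ as.character(.x$properties$zone_id))
  vals <- purrr::map_dbl(gj$features, ~ as.numeric(.x$properties$value))
  rings <- purrr::map(gj$features, function(f) {
    m <- do.call(rbind, purrr::map(f$geometry$coordinates[[1]], unlist))
    m[-nrow(m), , drop = FALSE] # drop the closing vertex
  })
  zone_map(ids, vals, rings)
}

#' Read a toxicity table or exposure factors from CSV
#'
#' Column names follow [toxicity_table()] (`pollutant`, `rfd`,
#' `air_standard`, `water_threshold`, `weight_cancer`, `weight_noncancer`)
#' and [exposure_factors()] (`age_class`, `ingestion_rate`, `frequency`,
#' `body_weight`).
#'
#' @param path CSV path.
#' @return A `toxicity_table` or `exposure_factors`.
#' @export
read_toxicity_table <- function(path) {
  if (!file.exists(path)) abort(paste0("toxicity table not found: ", path))
  toxicity_table(utils::read.csv(path))
}

#' @rdname read_toxicity_table
#' @export
read_exposure_factors <- function(path) {
  if (!file.exists(path)) abort(paste0("exposure factors file not found: ", path))
  exposure_factors(utils::read.csv(path))
}

#' Write all raw layers of a synthetic region to a directory
#'
#' Layer menu: soil point samples and tables as CSV, rasters as CSV with
#' JSON sidecars, zones as GeoJSON, ground truth as structured JSON.
#' Identical regions produce byte-identical files.
#'
#' @param region A `synthetic_region`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_region <- function(region, dir) {
  stopifnot(inherits(region, "synthetic_region"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  utils::write.csv(region$soil_points, p("soil_points.csv"), row.names = FALSE)
  write_vector(region$sites, p("sites.csv"))
  purrr::iwalk(region$air_conc, ~ write_raster(.x, p(paste0("air_", .y, ".csv"))))
  utils::write.csv(region$emissions, p("emissions.csv"), row.names = FALSE)
  utils::write.csv(region$water_exceedances, p("water_exceedances.csv"), row.names = FALSE)
  write_raster(region$noise, p("noise.csv"))
  write_raster(region$population, p("population.csv"))
  write_vector(region$districts, p("districts.geojson"))
  write_vector(region$water_units, p("water_units.geojson"))
  write_vector(region$census_blocks, p("census_blocks.geojson"))

  truth <- region$truth
  jsonlite::write_json(
    list(
      soil_hotspots = truth$soil$hotspots,
      air_hotspots = truth$air$hotspots,
      water_hotspots = truth$water$hotspots,
      noise_hotspots = truth$noise$hotspots,
      furrow = truth$furrow
    ),
    p("truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
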