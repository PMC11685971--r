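#' Write polygons with properties as GeoJSON
#'
#' Coordinates are planar meters in the world's local Cartesian frame; the
#' file carries no CRS member and is meant for round-tripping within this
#' toolchain (real-data workflows must supply layers already projected to a
#' metric CRS).
#'
#' @param polygons list of two-column vertex matrices.
#' @param properties data frame with one row per polygon.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polygons, properties, path) {
  features <- lapply(seq_along(polygons), function(i) {
    p <- as_polygon(polygons[[i]])
    ring <- rbind(p, p[1L, , drop = FALSE])
    props <- as.list(properties[i, , drop = FALSE])
    props <- lapply(props, function(v) if (inherits(v, "POSIXt"))
      format(v, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC") else v)
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

#' Read polygons and properties from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of Polygon features.
#' @return List with `polygons` (list of vertex matrices) and `properties`
#'   (data frame).
#' @export
read_geojson_polygons <- function(path) {
  obj <- jsonlite::read_json(path)
  stopifnot(identical(obj$type, "FeatureCollection"))
  polygons <- list(); props <- list()
  for (i in seq_along(obj$features)) {
    f <- obj$features[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature ", i, " is not a Polygon", call. = FALSE)
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    colnames(m) <- c("x", "y")
    polygons[[i]] <- as_polygon(m)
    props[[i]] <- as.data.frame(lapply(f$properties, function(v)
      if (is.null(v)) NA else v))
  }
  list(polygons = polygons, properties = do.call(rbind, props))
}

# plain-text CSV writer used by all stage outputs (deterministic formatting)
write_stage_csv <- function(df, path) {
  for (nm in names(df))
    if (inherits(df[[nm]], "POSIXt"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a synthetic world to plain-text files
#'
#' Writes the AOIs and exclusion layer as GeoJSON, the baseline population
#' raster as a cell-table CSV, per-image metadata and footprints, the
#' detections CSV, the ground truth CSVs, and the generating configuration as
#' JSON.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(aois = file.path(dir, "aois.geojson"),
             exclusions = file.path(dir, "exclusions.geojson"),
             population = file.path(dir, "population_baseline.csv"),
             pop_by_period = file.path(dir, "truth_population_by_period.csv"),
             expected_cars = file.path(dir, "truth_expected_cars.csv"),
             truth_detections = file.path(dir, "truth_detections.csv"),
             truth_points = file.path(dir, "truth_points.csv"),
             images = file.path(dir, "images.csv"),
             footprints = file.path(dir, "footprints.geojson"),
             detections = file.path(dir, "detections.csv"),
             config = file.path(dir, "world_config.json"))
  write_geojson_polygons(lapply(world$aois, `[[`, "poly"),
                         data.frame(aoi_id = vapply(world$aois, `[[`, "", "aoi_id"),
                                    oblast = vapply(world$aois, `[[`, "", "oblast")),
                         paths["aois"])
  write_geojson_polygons(world$exclusions$polygons, world$exclusions$tags,
                         paths["exclusions"])
  write_stage_csv(world$pop, paths["population"])
  write_stage_csv(world$truth$pop_by_period, paths["pop_by_period"])
  write_stage_csv(world$truth$expected_cars, paths["expected_cars"])
  write_stage_csv(world$truth$detections, paths["truth_detections"])
  write_stage_csv(world$truth$truth_points, paths["truth_points"])
  write_stage_csv(world$images, paths["images"])
  write_geojson_polygons(world$footprints[world$images$image_id],
                         data.frame(image_id = world$images$image_id),
                         paths["footprints"])
  write_stage_csv(world$detections, paths["detections"])
  cfg <- world$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  invisible(paths)
}
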