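#' Build the 1 x 1 km analysis grid for an AOI
#'
#' Lays axis-aligned square cells over the AOI with the grid origin snapped
#' to multiples of the cell size in the world frame (so cell identities are
#' reproducible across runs and periods), keeps the cells that intersect the
#' AOI, and fills each cell's baseline population by area-weighted
#' aggregation of the fine population raster. The aggregation conserves the
#' raster total: every fine cell distributes all of its people over the grid
#' cells it overlaps.
#'
#' @param aoi list with `aoi_id` and `poly` (convex AOI polygon), as stored in
#'   a `car_world`.
#' @param pop_cells fine population cell table (with `aoi_id`).
#' @param cell_m analysis cell size in meters (default 1000).
#' @return A `PopulationGrid` data frame: `aoi_id`, `cell_id`, `x0`, `y0`,
#'   `cell_m`, `baseline_people`.
#' @export
build_grid <- function(aoi, pop_cells, cell_m = 1000) {
  poly <- aoi$poly
  validate_polygon(poly)
  if ("aoi_id" %in% names(pop_cells))
    pop_cells <- pop_cells[pop_cells$aoi_id == aoi$aoi_id, , drop = FALSE]
  bb <- poly_bbox(poly)
  xs <- seq(floor(bb[1] / cell_m) * cell_m, ceiling(bb[3] / cell_m) * cell_m - cell_m,
            by = cell_m)
  ys <- seq(floor(bb[2] / cell_m) * cell_m, ceiling(bb[4] / cell_m) * cell_m - cell_m,
            by = cell_m)
  cells <- expand.grid(x0 = xs, y0 = ys)
  # keep cells that actually intersect the AOI
  keep <- vapply(seq_len(nrow(cells)), function(i) {
    cellp <- rect_poly(cells$x0[i], cells$y0[i],
                       cells$x0[i] + cell_m, cells$y0[i] + cell_m)
    polygon_intersection_area(cellp, poly) > 0
  }, logical(1))
  cells <- cells[keep, , drop = FALSE]
  fhalf <- pop_cells$cell_m / 2
  people <- vapply(seq_len(nrow(cells)), function(i) {
    w <- rect_overlap_area(pop_cells$x - fhalf, pop_cells$y - fhalf,
                           pop_cells$x + fhalf, pop_cells$y + fhalf,
                           cells$x0[i], cells$y0[i],
                           cells$x0[i] + cell_m, cells$y0[i] + cell_m) /
      pop_cells$cell_m^2
    sum(pop_cells$people * w)
  }, numeric(1))
  data.frame(aoi_id = aoi$aoi_id,
             cell_id = sprintf("%s_E%d_N%d", aoi$aoi_id,
                               as.integer(cells$x0 / cell_m),
                               as.integer(cells$y0 / cell_m)),
             x0 = cells$x0, y0 = cells$y0, cell_m = cell_m,
             baseline_people = people)
}

#' Count cars per grid cell for one image
#'
#' Assigns each (already confidence- and false-positive-filtered) detection
#' to exactly one cell using half-open intervals
#' \[x0, x0 + cell) x \[y0, y0 + cell), so a point on a shared edge goes to
#' the right/upper cell and is never double-counted. Cells whose covered
#' fraction by the image footprint is below `min_cover` are marked
#' uncovered; their counts must not be interpreted as observed zeros.
#' Detections outside all grid cells are dropped with a reported count.
#'
#' @param detections data frame with `x`, `y` (one image's detections).
#' @param grid a [build_grid()] result.
#' @param footprint the image footprint polygon.
#' @param min_cover minimum fraction of the cell area inside the footprint
#'   for the cell to count as covered (default 0.5).
#' @return Data frame `cell_id`, `n_cars`, `covered`, with attribute
#'   `n_outside` (detections falling outside the grid).
#' @export
count_cars_per_cell <- function(detections, grid, footprint, min_cover = 0.5) {
  cell_m <- grid$cell_m[1L]
  x0 <- floor(detections$x / cell_m) * cell_m
  y0 <- floor(detections$y / cell_m) * cell_m
  key <- paste(x0, y0)
  gkey <- paste(grid$x0, grid$y0)
  idx <- match(key, gkey)
  n_outside <- sum(is.na(idx))
  if (n_outside > 0)
    message(sprintf("dropped %d detections outside the analysis grid", n_outside))
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(grid))
  half_open_cover <- cell_cover_fraction(grid, footprint)
  out <- data.frame(cell_id = grid$cell_id, n_cars = counts,
                    covered = half_open_cover >= min_cover)
  attr(out, "n_outside") <- n_outside
  out
}

# fraction of each grid cell's area inside the footprint
cell_cover_fraction <- function(grid, footprint) {
  cell_m <- grid$cell_m[1L]
  if (is_axis_rect(footprint)) {
    bb <- poly_bbox(footprint)
    return(rect_overlap_area(grid$x0, grid$y0, grid$x0 + cell_m,
                             grid$y0 + cell_m, bb[1], bb[2], bb[3], bb[4]) /
             cell_m^2)
  }
  vapply(seq_len(nrow(grid)), function(i) {
    cellp <- rect_poly(grid$x0[i], grid$y0[i], grid$x0[i] + cell_m,
                       grid$y0[i] + cell_m)
    polygon_intersection_area(footprint, cellp) / cell_m^2
  }, numeric(1))
}

#' Monthly per-cell mean car counts
#'
#' For each AOI, cell, year and month, averages the per-image counts over the
#' images whose footprint covers that cell. Cells not covered by any image in
#' a month are absent from the result (never imputed as zero).
#'
#' @param counts_by_image data frame binding [count_cars_per_cell()] results
#'   with an `image_id` column.
#' @param images image metadata (`image_id`, `aoi_id`, `year`, `month`).
#' @return `CellMonthStat` data frame: `aoi_id`, `cell_id`, `year`, `month`,
#'   `mean_cars`, `n_images`.
#' @export
monthly_cell_means <- function(counts_by_image, images) {
  m <- match(counts_by_image$image_id, images$image_id)
  if (anyNA(m)) stop("counts reference unknown image_id", call. = FALSE)
  df <- data.frame(aoi_id = images$aoi_id[m], cell_id = counts_by_image$cell_id,
                   year = images$year[m], month = images$month[m],
                   n_cars = counts_by_image$n_cars,
                   covered = counts_by_image$covered)
  df <- df[df$covered, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(aoi_id = character(0), cell_id = character(0),
                      year = integer(0), month = integer(0),
                      mean_cars = numeric(0), n_images = integer(0)))
  agg <- stats::aggregate(n_cars ~ aoi_id + cell_id + year + month, data = df,
                          FUN = mean)
  cnt <- stats::aggregate(n_cars ~ aoi_id + cell_id + year + month, data = df,
                          FUN = length)
  agg$n_images <- cnt$n_cars
  names(agg)[names(agg) == "n_cars"] <- "mean_cars"
  agg[order(agg$aoi_id, agg$cell_id, agg$year, agg$month), , drop = FALSE]
}

#' Monthly AOI-level car density
#'
#' Density is cars per square kilometer of covered area: the sum of the
#' monthly per-cell means divided by the total area of the cells covered that
#' month (the denominator uses covered area only).
#'
#' @param stats a [monthly_cell_means()] result.
#' @param cell_m analysis cell size in meters.
#' @return Data frame `aoi_id`, `year`, `month`, `density`, `covered_km2`.
#' @export
monthly_aoi_density <- function(stats, cell_m = 1000) {
  if (nrow(stats) == 0L)
    return(data.frame(aoi_id = character(0), year = integer(0),
                      month = integer(0), density = numeric(0),
                      covered_km2 = numeric(0)))
  km2 <- (cell_m / 1000)^2
  tot <- stats::aggregate(mean_cars ~ aoi_id + year + month, data = stats,
                          FUN = sum)
  ncell <- stats::aggregate(cell_id ~ aoi_id + year + month, data = stats,
                            FUN = length)
  tot$covered_km2 <- ncell$cell_id * km2
  tot$density <- tot$mean_cars / tot$covered_km2
  tot[, c("aoi_id", "year", "month", "density", "covered_km2")]
}

#' Relative change in average car density vs a baseline year
#'
#' Computes, per unit (AOI or oblast) and target period (a whole year or its
#' calendar quarters), the percent change in average car density relative to
#' the baseline year. The AOI-level average density is the mean of its
#' monthly densities; at oblast level the AOI averages are first averaged
#' across the oblast's AOIs, then the change is computed (average-then-change).
#' Units lacking data in either period, or with a zero baseline density, are
#' reported with `pct_change = NA` and a reason — never as zero change.
#'
#' @param stats a [monthly_cell_means()] result. For a war-period analysis
#'   the target-year stats should be built from images acquired on/after the
#'   cut date (see [run_pipeline()]'s `cut_date`).
#' @param baseline_year baseline calendar year (default 2019).
#' @param target_year comparison year.
#' @param level `"aoi"` or `"oblast"`.
#' @param period `"year"` or `"quarter"`.
#' @param oblasts named character vector mapping `aoi_id` to oblast (required
#'   for `level = "oblast"`).
#' @param cell_m analysis cell size in meters.
#' @return `DensityChange` data frame: `unit`, `level`, `period`,
#'   `baseline_density`, `period_density`, `pct_change`, `reason`.
#' @export
relative_density_change <- function(stats, baseline_year = 2019, target_year,
                                    level = c("aoi", "oblast"),
                                    period = c("year", "quarter"),
                                    oblasts = NULL, cell_m = 1000) {
  level <- match.arg(level)
  period <- match.arg(period)
  dens <- monthly_aoi_density(stats, cell_m = cell_m)
  base <- dens[dens$year == baseline_year, , drop = FALSE]
  targ <- dens[dens$year == target_year, , drop = FALSE]
  targ$period <- if (period == "year") as.character(target_year)
  else sprintf("%dQ%d", target_year, (targ$month - 1) %/% 3 + 1)
  periods <- sort(unique(targ$period))
  if (period == "year" && nrow(targ) == 0L) periods <- as.character(target_year)

  aoi_mean <- function(d) {
    if (nrow(d) == 0L) return(stats::setNames(numeric(0), character(0)))
    a <- stats::aggregate(density ~ aoi_id, data = d, FUN = mean)
    stats::setNames(a$density, a$aoi_id)
  }
  base_aoi <- aoi_mean(base)

  units_of <- function(aois) {
    if (level == "aoi") stats::setNames(aois, aois)
    else {
      if (is.null(oblasts)) stop("oblast level needs an aoi->oblast map",
                                 call. = FALSE)
      stats::setNames(unname(oblasts[aois]), aois)
    }
  }
  all_aois <- sort(unique(c(names(base_aoi), targ$aoi_id, stats$aoi_id)))
  unit_map <- units_of(all_aois)
  out <- list()
  for (pd in periods) {
    targ_aoi <- aoi_mean(targ[targ$period == pd, , drop = FALSE])
    for (u in sort(unique(unit_map))) {
      members <- names(unit_map)[unit_map == u]
      b_vals <- base_aoi[names(base_aoi) %in% members]
      t_vals <- targ_aoi[names(targ_aoi) %in% members]
      b <- if (length(b_vals)) mean(b_vals) else NA_real_
      tg <- if (length(t_vals)) mean(t_vals) else NA_real_
      if (is.na(b) || is.na(tg)) {
        pc <- NA_real_
        reason <- "missing data in baseline and/or target period"
      } else if (b == 0) {
        pc <- NA_real_
        reason <- "baseline density is zero; relative change undefined"
      } else {
        pc <- 100 * (tg - b) / b
        reason <- ""
      }
      out[[paste(u, pd)]] <- data.frame(unit = u, level = level, period = pd,
                                        baseline_density = b,
                                        period_density = tg,
                                        pct_change = pc, reason = reason)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
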