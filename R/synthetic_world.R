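#' Configure a synthetic multi-city world
#'
#' Builds the configuration object consumed by [generate_world()]. The
#' synthetic world emulates the data situation of satellite-based displacement
#' monitoring: several cities (areas of interest, AOIs) with heterogeneous
#' 100 m population surfaces, a monotone population-to-visible-cars link with
#' Poisson count noise, partial image footprints with quality metadata
#' (resolution, off-nadir and sun-elevation angles, cloud fraction, snow),
#' false-positive detections injected inside tagged exclusion polygons, and a
#' known per-city displacement scenario between a baseline year and later
#' years. Coordinates are planar meters in a local Cartesian frame.
#'
#' @param n_cities number of AOIs; the first half is labelled oblast "East",
#'   the rest "West".
#' @param aoi_size_km side length of each (square) AOI, km.
#' @param pop_cell_m fine population raster cell size, meters (default 100).
#' @param pop_model list: `total_range` (per-city population range),
#'   `n_hotspots` (density hotspots per city), `hotspot_sd_frac` (hotspot
#'   spread as a fraction of the AOI side), `floor_frac` (share of people
#'   spread uniformly).
#' @param link_model list: `a`, `b` for the monotone link
#'   E\[cars\] = a * people^b per fine cell, and `noise` ("poisson" or "none").
#' @param image_model list: `years`, `months`, `per_month_lambda` (Poisson
#'   mean of images per city-month), `side_frac_range` (footprint side as a
#'   fraction of the AOI side), `gsd_levels`/`gsd_probs`, `off_nadir_range`,
#'   `sun_elev_range`, `cloud_beta` (Beta parameters of cloud fraction),
#'   `snow_prob_winter`, `snow_prob_other`.
#' @param fp_model list: `intensity_km2` (false positives per km^2 of
#'   exclusion area), `margin_m` (placement margin inside polygon boundaries),
#'   `score_beta` (Beta parameters of false-positive confidence scores).
#' @param score_model list: `true` Beta parameters of true-car scores
#'   (skewed high), mixture with `fp_model$score_beta` makes threshold tuning
#'   informative.
#' @param exclusion_model list: `n_per_city`, `size_frac` range of polygon
#'   side as fraction of AOI side, `tags` data frame of key/value pairs to
#'   sample from.
#' @param scenario data frame with columns `aoi_id` (or missing for all),
#'   `year`, `multiplier`; population in `year` is the baseline surface scaled
#'   by `multiplier`. `NULL` builds the default East-drop/West-rise scenario
#'   (baseline 2019 at 1, 2020 at 0.9 everywhere, 2022 at 0.45 East / 1.8
#'   West).
#' @param other_class_intensity_km2 intensity of non-car ("bus") clutter
#'   detections per covered km^2; these exercise the class filter.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   world bit-identically.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_cities = 4,
                         aoi_size_km = 5,
                         pop_cell_m = 100,
                         pop_model = list(total_range = c(4e4, 1.2e5),
                                          n_hotspots = 3,
                                          hotspot_sd_frac = 0.15,
                                          floor_frac = 0.10),
                         link_model = list(a = 0.04, b = 1, noise = "poisson"),
                         image_model = list(years = c(2019, 2020, 2022),
                                            months = 3:8,
                                            per_month_lambda = 1.5,
                                            side_frac_range = c(0.55, 1),
                                            gsd_levels = c(0.3, 0.4, 0.5),
                                            gsd_probs = c(0.35, 0.35, 0.30),
                                            off_nadir_range = c(5, 40),
                                            sun_elev_range = c(20, 60),
                                            cloud_beta = c(0.6, 8),
                                            snow_prob_winter = 0.3,
                                            snow_prob_other = 0.02),
                         fp_model = list(intensity_km2 = 25,
                                         margin_m = 5,
                                         score_beta = c(2.5, 6)),
                         score_model = list(true = c(6, 2.5)),
                         exclusion_model = list(n_per_city = 2,
                                                size_frac = c(0.08, 0.18),
                                                tags = data.frame(
                                                  key = c("natural", "landuse", "leisure", "natural", "aeroway"),
                                                  value = c("water", "farmland", "park", "wood", "aerodrome"))),
                         scenario = NULL,
                         other_class_intensity_km2 = 2,
                         seed = 1L) {
  cfg <- list(n_cities = n_cities, aoi_size_km = aoi_size_km,
              pop_cell_m = pop_cell_m, pop_model = pop_model,
              link_model = link_model, image_model = image_model,
              fp_model = fp_model, score_model = score_model,
              exclusion_model = exclusion_model, scenario = scenario,
              other_class_intensity_km2 = other_class_intensity_km2,
              seed = as.integer(seed))
  class(cfg) <- "world_config"
  validate_world_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

validate_world_config <- function(cfg) {
  if (!is.numeric(cfg$n_cities) || cfg$n_cities < 1)
    config_error("n_cities", "must be a positive count")
  if (!is.numeric(cfg$aoi_size_km) || cfg$aoi_size_km <= 0)
    config_error("aoi_size_km", "must be positive")
  if (!is.numeric(cfg$pop_cell_m) || cfg$pop_cell_m <= 0)
    config_error("pop_cell_m", "must be positive")
  if (cfg$link_model$a < 0) config_error("link_model", "link coefficient a must be >= 0")
  if (!cfg$link_model$noise %in% c("poisson", "none"))
    config_error("link_model", "noise must be 'poisson' or 'none'")
  im <- cfg$image_model
  if (any(im$side_frac_range <= 0) || any(im$side_frac_range > 1))
    config_error("image_model", "side_frac_range must lie in (0, 1]")
  if (any(im$cloud_beta <= 0))
    config_error("image_model", "cloud_beta parameters must be positive")
  if (cfg$fp_model$intensity_km2 < 0)
    config_error("fp_model", "intensity_km2 must be >= 0")
  if (cfg$fp_model$margin_m < 0)
    config_error("fp_model", "margin_m must be >= 0")
  if (!is.null(cfg$scenario)) {
    if (!all(c("year", "multiplier") %in% names(cfg$scenario)))
      config_error("scenario", "needs columns year and multiplier")
    if (any(cfg$scenario$multiplier < 0))
      config_error("scenario", "multipliers must be >= 0")
  }
  invisible(TRUE)
}

# monotone link: expected visible cars in a fine cell of `people` residents
link_expected_cars <- function(people, link_model) {
  link_model$a * people^link_model$b
}

default_scenario <- function(aoi_ids, oblasts, years) {
  base_year <- min(years)
  rows <- list()
  for (y in years) {
    m <- if (y == base_year) rep(1, length(aoi_ids))
    else if (y == sort(years)[2] && length(years) > 2) rep(0.9, length(aoi_ids))
    else ifelse(oblasts == "East", 0.45, 1.8)
    rows[[as.character(y)]] <- data.frame(aoi_id = aoi_ids, year = y,
                                          multiplier = m)
  }
  do.call(rbind, rows)
}

#' Apply a displacement scenario to a baseline population surface
#'
#' Scales each fine cell's population by its city (or cell) multiplier for
#' every period in the scenario. Totals scale accordingly: the displaced city
#' total is exactly the multiplier times the baseline total for city-level
#' scenarios.
#'
#' @param baseline_cells data frame of fine population cells with columns
#'   `aoi_id`, `x`, `y`, `cell_m`, `people` (the baseline surface).
#' @param scenario data frame with columns `year`, `multiplier` and either
#'   `aoi_id` (city-level multipliers) or `aoi_id`, `x`, `y` (cell-level).
#' @return Long data frame: `aoi_id`, `x`, `y`, `cell_m`, `year`, `people`.
#' @export
apply_displacement_scenario <- function(baseline_cells, scenario) {
  if (any(scenario$multiplier < 0))
    stop("scenario multipliers must be >= 0", call. = FALSE)
  cell_level <- all(c("x", "y") %in% names(scenario))
  out <- lapply(unique(scenario$year), function(y) {
    sc <- scenario[scenario$year == y, , drop = FALSE]
    cells <- baseline_cells
    if (cell_level) {
      key <- paste(cells$aoi_id, cells$x, cells$y)
      skey <- paste(sc$aoi_id, sc$x, sc$y)
      mult <- sc$multiplier[match(key, skey)]
    } else if ("aoi_id" %in% names(sc)) {
      mult <- sc$multiplier[match(cells$aoi_id, sc$aoi_id)]
    } else {
      mult <- rep(sc$multiplier[1L], nrow(cells))
    }
    if (anyNA(mult))
      stop("scenario does not cover every cell/city for year ", y, call. = FALSE)
    data.frame(aoi_id = cells$aoi_id, x = cells$x, y = cells$y,
               cell_m = cells$cell_m, year = y, people = cells$people * mult)
  })
  do.call(rbind, out)
}

#' Generate a synthetic world
#'
#' Realizes the configured world: AOI polygons, the fine baseline population
#' raster (as a cell table), tagged exclusion polygons, per-period image
#' snapshots with metadata and sampled detections, and the full ground truth
#' (per-period populations, per-cell expected cars, and the true-car /
#' false-positive label of every detection). Detections under full cloud
#' obstruction are suppressed; partial cloud thins expected counts by
#' (1 - cloud fraction).
#'
#' @param config a [world_config()].
#' @return An object of class `car_world`: a list with elements `config`,
#'   `aois` (list of `aoi_id`, `oblast`, `poly`), `pop` (baseline fine-cell
#'   table), `exclusions` (an [exclusion_layer()]), `images` (metadata data
#'   frame), `footprints` (named list of polygons), `detections` (data frame
#'   `det_id`, `image_id`, `x`, `y`, `score`, `class`), and `truth` (list:
#'   `pop_by_period`, `expected_cars`, `detections` with `is_fp`,
#'   `truth_points` per image).
#' @export
generate_world <- function(config = world_config()) {
  validate_world_config(config)
  set.seed(config$seed)
  side_m <- config$aoi_size_km * 1000
  gap_m <- 2000
  n <- as.integer(config$n_cities)
  aoi_ids <- sprintf("city%02d", seq_len(n))
  oblasts <- ifelse(seq_len(n) <= ceiling(n / 2), "East", "West")

  aois <- vector("list", n)
  pop_list <- vector("list", n)
  excl_polys <- list()
  excl_tags <- list()
  for (i in seq_len(n)) {
    x0 <- (i - 1) * (side_m + gap_m)
    poly <- rect_poly(x0, 0, x0 + side_m, side_m)
    aois[[i]] <- list(aoi_id = aoi_ids[i], oblast = oblasts[i], poly = poly)
    pop_list[[i]] <- make_pop_surface(aoi_ids[i], x0, 0, side_m,
                                      config$pop_cell_m, config$pop_model)
    em <- config$exclusion_model
    for (k in seq_len(em$n_per_city)) {
      w <- stats::runif(1, em$size_frac[1], em$size_frac[2]) * side_m
      h <- stats::runif(1, em$size_frac[1], em$size_frac[2]) * side_m
      ex0 <- x0 + stats::runif(1, 0, side_m - w)
      ey0 <- stats::runif(1, 0, side_m - h)
      tag <- em$tags[sample.int(nrow(em$tags), 1L), , drop = FALSE]
      excl_polys[[length(excl_polys) + 1L]] <- rect_poly(ex0, ey0, ex0 + w, ey0 + h)
      excl_tags[[length(excl_tags) + 1L]] <-
        data.frame(aoi_id = aoi_ids[i], key = tag$key, value = tag$value)
    }
  }
  pop <- do.call(rbind, pop_list)
  exclusions <- exclusion_layer(excl_polys, do.call(rbind, excl_tags))

  # people cannot live under water/forest: zero cells whose center is excluded
  if (length(excl_polys)) {
    inside <- rep(FALSE, nrow(pop))
    for (p in excl_polys)
      inside <- inside | points_in_polygon(pop$x, pop$y, p)
    pop$people[inside] <- 0
  }

  scenario <- config$scenario
  if (is.null(scenario))
    scenario <- default_scenario(aoi_ids, oblasts, config$image_model$years)
  pop_by_period <- apply_displacement_scenario(pop, scenario)

  expected_cars <- pop_by_period
  expected_cars$expected_cars <-
    link_expected_cars(expected_cars$people, config$link_model)
  expected_cars$people <- NULL

  im <- config$image_model
  images <- list(); footprints <- list()
  dets <- list(); truth_dets <- list(); truth_points <- list()
  img_n <- 0L
  for (i in seq_len(n)) {
    aoi <- aois[[i]]
    bb <- poly_bbox(aoi$poly)
    for (year in im$years) {
      pop_y <- pop_by_period[pop_by_period$year == year &
                               pop_by_period$aoi_id == aoi$aoi_id, ]
      year_months <- if (is.list(im$months)) im$months[[as.character(year)]]
      else im$months
      for (month in year_months) {
        n_img <- stats::rpois(1L, im$per_month_lambda)
        for (k in seq_len(n_img)) {
          img_n <- img_n + 1L
          image_id <- sprintf("img%05d", img_n)
          fx <- stats::runif(1, im$side_frac_range[1], im$side_frac_range[2]) * side_m
          fy <- stats::runif(1, im$side_frac_range[1], im$side_frac_range[2]) * side_m
          ox <- bb[1] + stats::runif(1, 0, side_m - fx)
          oy <- bb[2] + stats::runif(1, 0, side_m - fy)
          footprint <- rect_poly(ox, oy, ox + fx, oy + fy)
          snow_p <- if (month %in% c(1, 2, 12)) im$snow_prob_winter else im$snow_prob_other
          meta <- data.frame(
            image_id = image_id, aoi_id = aoi$aoi_id, oblast = aoi$oblast,
            acquired_at = as.POSIXct(sprintf("%d-%02d-%02d 08:%02d:00", year,
                                             month, sample(5:25, 1L),
                                             sample(0:59, 1L)),
                                     tz = "UTC"),
            year = year, month = month,
            gsd_m = sample(im$gsd_levels, 1L, prob = im$gsd_probs),
            off_nadir_deg = stats::runif(1, im$off_nadir_range[1], im$off_nadir_range[2]),
            sun_elev_deg = stats::runif(1, im$sun_elev_range[1], im$sun_elev_range[2]),
            cloud_frac = stats::rbeta(1, im$cloud_beta[1], im$cloud_beta[2]),
            snow = stats::runif(1) < snow_p)
          images[[img_n]] <- meta
          footprints[[image_id]] <- footprint
          sm <- sample_detections(
            image = c(as.list(meta), list(footprint = footprint)),
            cells = pop_y, link_model = config$link_model,
            fp_model = config$fp_model, exclusions = exclusions,
            score_model = config$score_model,
            other_class_intensity_km2 = config$other_class_intensity_km2)
          if (nrow(sm$detections)) {
            dets[[length(dets) + 1L]] <- sm$detections
            truth_dets[[length(truth_dets) + 1L]] <-
              sm$detections[, c("det_id", "image_id", "is_fp")]
          }
          if (nrow(sm$truth_points))
            truth_points[[length(truth_points) + 1L]] <- sm$truth_points
        }
      }
    }
  }
  images <- if (img_n) do.call(rbind, images) else empty_images()
  detections <- if (length(dets)) do.call(rbind, dets) else empty_detections()
  detections$det_id <- if (nrow(detections))
    sprintf("det%07d", seq_len(nrow(detections))) else character(0)
  truth_detections <- detections[, c("det_id", "image_id", "is_fp")]
  detections$is_fp <- NULL
  truth_points <- if (length(truth_points)) do.call(rbind, truth_points)
  else data.frame(image_id = character(0), x = numeric(0), y = numeric(0))

  structure(list(config = config, aois = aois, pop = pop,
                 exclusions = exclusions, images = images,
                 footprints = footprints, detections = detections,
                 truth = list(pop_by_period = pop_by_period,
                              expected_cars = expected_cars,
                              detections = truth_detections,
                              truth_points = truth_points,
                              scenario = scenario)),
            class = "car_world")
}

empty_images <- function() {
  data.frame(image_id = character(0), aoi_id = character(0),
             oblast = character(0),
             acquired_at = as.POSIXct(character(0), tz = "UTC"),
             year = integer(0), month = integer(0), gsd_m = numeric(0),
             off_nadir_deg = numeric(0), sun_elev_deg = numeric(0),
             cloud_frac = numeric(0), snow = logical(0))
}

empty_detections <- function() {
  data.frame(det_id = character(0), image_id = character(0), x = numeric(0),
             y = numeric(0), score = numeric(0), class = character(0),
             is_fp = logical(0))
}

# Gaussian-hotspot population surface on a fine square raster, scaled to a
# sampled city total. Returns the cell table (cell centers).
make_pop_surface <- function(aoi_id, x0, y0, side_m, cell_m, pop_model) {
  ncell <- floor(side_m / cell_m)
  cx <- x0 + (seq_len(ncell) - 0.5) * cell_m
  cy <- y0 + (seq_len(ncell) - 0.5) * cell_m
  grid <- expand.grid(x = cx, y = cy)
  total <- stats::runif(1, pop_model$total_range[1], pop_model$total_range[2])
  dens <- rep(pop_model$floor_frac / (ncell^2), nrow(grid))
  sdm <- pop_model$hotspot_sd_frac * side_m
  w <- stats::runif(pop_model$n_hotspots)
  w <- (1 - pop_model$floor_frac) * w / sum(w)
  for (h in seq_len(pop_model$n_hotspots)) {
    hx <- stats::runif(1, x0 + 0.2 * side_m, x0 + 0.8 * side_m)
    hy <- stats::runif(1, y0 + 0.2 * side_m, y0 + 0.8 * side_m)
    g <- exp(-((grid$x - hx)^2 + (grid$y - hy)^2) / (2 * sdm^2))
    dens <- dens + w[h] * g / sum(g)
  }
  data.frame(aoi_id = aoi_id, x = grid$x, y = grid$y, cell_m = cell_m,
             people = total * dens / sum(dens))
}

#' Sample detections for one image
#'
#' Draws car detections over the fine population cells covered by the image
#' footprint. The expected count in a cell is the link-model mean attenuated
#' by the covered fraction of the cell and by (1 - cloud fraction); a fully
#' clouded image yields no detections. Detection points are uniform within
#' the cell-footprint overlap (displaced from the true car position by a
#' small localization jitter), true-car scores and false-positive scores come
#' from their configured Beta distributions, and false positives are placed
#' at least `fp_model$margin_m` inside exclusion polygons intersecting the
#' footprint.
#'
#' @param image list with at least `image_id`, `aoi_id`, `cloud_frac`, and
#'   `footprint` (polygon matrix).
#' @param cells fine population cell table (`aoi_id`, `x`, `y`, `cell_m`,
#'   `people`) for the image's period.
#' @param link_model,fp_model,score_model see [world_config()].
#' @param exclusions an [exclusion_layer()] or `NULL`.
#' @param other_class_intensity_km2 clutter intensity for non-car classes.
#' @param seed optional integer; when given, sampling is restarted from it.
#' @return list with `detections` (data frame `det_id`, `image_id`, `x`, `y`,
#'   `score`, `class`, `is_fp`) and `truth_points` (true car locations).
#' @export
sample_detections <- function(image, cells, link_model,
                              fp_model = list(intensity_km2 = 0, margin_m = 5,
                                              score_beta = c(2.5, 6)),
                              exclusions = NULL,
                              score_model = list(true = c(6, 2.5)),
                              other_class_intensity_km2 = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fp <- image$footprint
  empty <- list(detections = empty_detections(),
                truth_points = data.frame(image_id = character(0),
                                          x = numeric(0), y = numeric(0)))
  if (image$cloud_frac >= 1) return(empty)
  att <- 1 - image$cloud_frac

  cells <- cells[cells$aoi_id == image$aoi_id, , drop = FALSE]
  half <- cells$cell_m / 2
  if (is_axis_rect(fp)) {
    bb <- poly_bbox(fp)
    frac <- rect_overlap_area(cells$x - half, cells$y - half,
                              cells$x + half, cells$y + half,
                              bb[1], bb[2], bb[3], bb[4]) / cells$cell_m^2
  } else {
    frac <- vapply(seq_len(nrow(cells)), function(i) {
      cellp <- rect_poly(cells$x[i] - half[i], cells$y[i] - half[i],
                         cells$x[i] + half[i], cells$y[i] + half[i])
      polygon_intersection_area(fp, cellp) / cells$cell_m[i]^2
    }, numeric(1))
  }
  lambda <- link_expected_cars(cells$people, link_model) * frac * att
  ncar <- if (link_model$noise == "poisson") stats::rpois(length(lambda), lambda)
  else round(lambda)
  tot <- sum(ncar)

  true_pts <- NULL
  if (tot > 0) {
    idx <- rep.int(seq_along(ncar), ncar)
    if (is_axis_rect(fp)) {
      bb <- poly_bbox(fp)
      lx <- pmax(cells$x[idx] - half[idx], bb[1])
      ux <- pmin(cells$x[idx] + half[idx], bb[3])
      ly <- pmax(cells$y[idx] - half[idx], bb[2])
      uy <- pmin(cells$y[idx] + half[idx], bb[4])
      px <- stats::runif(tot, lx, ux)
      py <- stats::runif(tot, ly, uy)
    } else {
      px <- py <- numeric(tot)
      for (k in seq_len(tot)) {
        i <- idx[k]
        repeat {
          xx <- stats::runif(1, cells$x[i] - half[i], cells$x[i] + half[i])
          yy <- stats::runif(1, cells$y[i] - half[i], cells$y[i] + half[i])
          if (points_in_polygon(xx, yy, fp)) break
        }
        px[k] <- xx; py[k] <- yy
      }
    }
    # keep true cars out of exclusion polygons (uninhabitable areas), with a
    # buffer wider than the localization jitter so jittered detections cannot
    # cross into an exclusion polygon
    if (!is.null(exclusions) && length(exclusions$polygons)) {
      bad <- rep(FALSE, tot)
      for (p in exclusions$polygons)
        bad <- bad | points_in_polygon(px, py, p) |
          dist_to_boundary(px, py, p) < 2.5
      px <- px[!bad]; py <- py[!bad]
      tot <- length(px)
    }
    true_pts <- cbind(px, py)
  }

  det <- list()
  if (!is.null(true_pts) && nrow(true_pts) > 0) {
    jx <- stats::rnorm(nrow(true_pts), 0, 0.5)
    jy <- stats::rnorm(nrow(true_pts), 0, 0.5)
    jx <- pmin(pmax(jx, -2), 2); jy <- pmin(pmax(jy, -2), 2)
    det[["true"]] <- data.frame(
      image_id = image$image_id,
      x = true_pts[, 1] + jx, y = true_pts[, 2] + jy,
      score = stats::rbeta(nrow(true_pts), score_model$true[1], score_model$true[2]),
      class = "small car", is_fp = FALSE)
  }

  if (!is.null(exclusions) && fp_model$intensity_km2 > 0) {
    excl_aoi <- which(exclusions$tags$aoi_id == image$aoi_id)
    for (j in excl_aoi) {
      poly <- exclusions$polygons[[j]]
      reg <- clip_polygon_convex(poly, fp)
      if (is.null(reg)) next
      area_km2 <- polygon_area_safe(reg) / 1e6
      nfp <- stats::rpois(1L, fp_model$intensity_km2 * area_km2 * att)
      if (nfp == 0L) next
      pts <- matrix(numeric(0), ncol = 2L)
      tries <- 0L
      while (nrow(pts) < nfp && tries < 200L) {
        cand <- sample_points_in_polygon(nfp, reg)
        ok <- dist_to_boundary(cand[, 1], cand[, 2], poly) >= fp_model$margin_m
        pts <- rbind(pts, cand[ok, , drop = FALSE])
        tries <- tries + 1L
      }
      if (nrow(pts) == 0L) next
      pts <- pts[seq_len(min(nfp, nrow(pts))), , drop = FALSE]
      det[[paste0("fp", j)]] <- data.frame(
        image_id = image$image_id, x = pts[, 1], y = pts[, 2],
        score = stats::rbeta(nrow(pts), fp_model$score_beta[1], fp_model$score_beta[2]),
        class = "small car", is_fp = TRUE)
    }
  }

  if (other_class_intensity_km2 > 0) {
    area_km2 <- polygon_area(fp) / 1e6
    nb <- stats::rpois(1L, other_class_intensity_km2 * area_km2 * att)
    if (nb > 0L) {
      pts <- sample_points_in_polygon(nb, fp)
      det[["other"]] <- data.frame(
        image_id = image$image_id, x = pts[, 1], y = pts[, 2],
        score = stats::rbeta(nb, 4, 4), class = "bus", is_fp = NA)
    }
  }

  if (length(det)) {
    detections <- do.call(rbind, det)
    rownames(detections) <- NULL
    detections <- cbind(det_id = sprintf("%s_d%05d", image$image_id,
                                         seq_len(nrow(detections))),
                        detections)
  } else {
    detections <- empty_detections()
  }
  truth_points <- if (!is.null(true_pts) && nrow(true_pts) > 0)
    data.frame(image_id = image$image_id, x = true_pts[, 1], y = true_pts[, 2])
  else empty$truth_points
  list(detections = detections, truth_points = truth_points)
}
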