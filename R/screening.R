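#' Screening rules
#'
#' Thresholds applied by [screen_images()]. Defaults follow the study design:
#' images covering less than 50% of the AOI population are unrepresentative;
#' images with effective cloud obstruction of 0.95 or more are dropped (the
#' automated stand-in for "fully obstructed" manual inspection, with cloud
#' fractions in \[`cloud_review`, `cloud_drop`) flagged for review); kept
#' images with fewer than 10 detections are flagged as suspicious; images
#' covering less than 1% of the AOI area violate the ingest contract.
#'
#' @param min_pop_coverage minimum population-coverage index (percent).
#' @param cloud_drop cloud fraction at or above which an image is dropped.
#' @param cloud_review cloud fraction at or above which a kept image is
#'   flagged for manual review.
#' @param low_count detection count below which a kept image is flagged.
#' @param min_area_pct minimum AOI area coverage (percent) at ingest.
#' @return A list of class `screening_rules`.
#' @export
screening_rules <- function(min_pop_coverage = 50, cloud_drop = 0.95,
                            cloud_review = 0.5, low_count = 10,
                            min_area_pct = 1) {
  structure(list(min_pop_coverage = min_pop_coverage, cloud_drop = cloud_drop,
                 cloud_review = cloud_review, low_count = low_count,
                 min_area_pct = min_area_pct), class = "screening_rules")
}

#' Population-coverage index of an image footprint
#'
#' Percent of an AOI's baseline population lying under the image footprint:
#' 100 times the people inside the footprint-AOI intersection divided by the
#' people in the AOI. Fine cells straddling the boundary contribute in
#' proportion to the intersected fraction of their area (unbiased under
#' uniform within-cell density).
#'
#' @param footprint image footprint polygon (vertex matrix).
#' @param pop_cells fine population cell table with `x`, `y`, `cell_m`,
#'   `people` (already restricted to, or carrying, the image's AOI).
#' @param aoi AOI polygon (vertex matrix); must be convex (AOIs are
#'   rectangles in this frame).
#' @param aoi_id optional; when given and `pop_cells` has an `aoi_id` column,
#'   the cells are restricted to it.
#' @return Coverage index in \[0, 100\].
#' @export
population_coverage_index <- function(footprint, pop_cells, aoi,
                                      aoi_id = NULL) {
  if (!is.null(aoi_id) && "aoi_id" %in% names(pop_cells))
    pop_cells <- pop_cells[pop_cells$aoi_id == aoi_id, , drop = FALSE]
  w_aoi <- cell_overlap_fractions(pop_cells, aoi)
  denom <- sum(pop_cells$people * w_aoi)
  if (denom <= 0)
    stop("AOI has zero total population; coverage index undefined",
         call. = FALSE)
  region <- clip_polygon_convex(footprint, aoi)
  if (is.null(region)) return(0)
  w_fp <- cell_overlap_fractions(pop_cells, region)
  100 * sum(pop_cells$people * w_fp) / denom
}

# fraction of each fine cell's area covered by `poly` (rect fast path)
cell_overlap_fractions <- function(pop_cells, poly) {
  half <- pop_cells$cell_m / 2
  if (is_axis_rect(poly)) {
    bb <- poly_bbox(poly)
    return(rect_overlap_area(pop_cells$x - half, pop_cells$y - half,
                             pop_cells$x + half, pop_cells$y + half,
                             bb[1], bb[2], bb[3], bb[4]) / pop_cells$cell_m^2)
  }
  bb <- poly_bbox(poly)
  frac <- numeric(nrow(pop_cells))
  cand <- which(pop_cells$x + half >= bb[1] & pop_cells$x - half <= bb[3] &
                  pop_cells$y + half >= bb[2] & pop_cells$y - half <= bb[4])
  for (i in cand) {
    cellp <- rect_poly(pop_cells$x[i] - half[i], pop_cells$y[i] - half[i],
                       pop_cells$x[i] + half[i], pop_cells$y[i] + half[i])
    frac[i] <- polygon_intersection_area(poly, cellp) / pop_cells$cell_m[i]^2
  }
  frac
}

#' Percent of AOI area covered by an image footprint
#'
#' @param footprint footprint polygon.
#' @param aoi AOI polygon (convex).
#' @return 100 * area(footprint intersected with AOI) / area(AOI).
#' @export
aoi_area_coverage <- function(footprint, aoi) {
  a <- polygon_area(aoi)
  if (a <= 0) stop("degenerate AOI with zero area", call. = FALSE)
  100 * polygon_intersection_area(footprint, aoi) / a
}

#' Screen images for representativeness, cloud obstruction and low counts
#'
#' Every image receives exactly one decision: `drop_cloud` (effective cloud
#' obstruction at or above the drop threshold), `drop_area` (footprint covers
#' less than the ingest minimum of the AOI area), `drop_population`
#' (population-coverage index below the minimum), or `keep`. Kept images with
#' fewer than `low_count` detections additionally carry `flag_low_count`
#' (suspicious false zeros/low counts), and kept images in the cloud review
#' band carry `flag_cloud_review`. Dropped images are retained in the report
#' with their reason, never silently discarded.
#'
#' @param images image metadata data frame (`image_id`, `aoi_id`,
#'   `cloud_frac`, and optionally `n_detections`).
#' @param footprints named list of footprint polygons, keyed by `image_id`.
#' @param pop_cells fine population cell table (with `aoi_id`).
#' @param aois list of AOIs (`aoi_id`, `poly`) as in a `car_world`.
#' @param rules a [screening_rules()].
#' @return A `ScreeningReport` data frame: `image_id`, `aoi_id`, `p_pct`,
#'   `area_pct`, `decision`, `reason`, `flag_low_count`, `flag_cloud_review`.
#' @export
screen_images <- function(images, footprints, pop_cells, aois,
                          rules = screening_rules()) {
  aoi_polys <- stats::setNames(lapply(aois, `[[`, "poly"),
                               vapply(aois, `[[`, "", "aoi_id"))
  n <- nrow(images)
  p_pct <- area_pct <- rep(NA_real_, n)
  decision <- reason <- character(n)
  flag_low <- flag_cloud <- rep(FALSE, n)
  has_counts <- "n_detections" %in% names(images)
  for (i in seq_len(n)) {
    fp <- footprints[[images$image_id[i]]]
    aoi <- aoi_polys[[images$aoi_id[i]]]
    area_pct[i] <- aoi_area_coverage(fp, aoi)
    p_pct[i] <- population_coverage_index(fp, pop_cells, aoi,
                                          aoi_id = images$aoi_id[i])
    cf <- images$cloud_frac[i]
    if (cf >= rules$cloud_drop) {
      decision[i] <- "drop_cloud"
      reason[i] <- sprintf("cloud fraction %.2f >= %.2f (fully obstructed)",
                           cf, rules$cloud_drop)
    } else if (area_pct[i] < rules$min_area_pct) {
      decision[i] <- "drop_area"
      reason[i] <- sprintf("footprint covers %.2f%% of AOI area (< %g%% ingest minimum)",
                           area_pct[i], rules$min_area_pct)
    } else if (p_pct[i] < rules$min_pop_coverage) {
      decision[i] <- "drop_population"
      reason[i] <- sprintf("population coverage %.1f%% < %g%% (unrepresentative)",
                           p_pct[i], rules$min_pop_coverage)
    } else {
      decision[i] <- "keep"
      reason[i] <- "kept"
      if (cf >= rules$cloud_review) {
        flag_cloud[i] <- TRUE
        reason[i] <- sprintf("kept; cloud fraction %.2f flagged for review", cf)
      }
      if (has_counts && !is.na(images$n_detections[i]) &&
          images$n_detections[i] < rules$low_count) {
        flag_low[i] <- TRUE
        reason[i] <- sprintf("%s; low detection count (N = %d < %g)",
                             reason[i], images$n_detections[i], rules$low_count)
      }
    }
  }
  data.frame(image_id = images$image_id, aoi_id = images$aoi_id,
             p_pct = p_pct, area_pct = area_pct, decision = decision,
             reason = reason, flag_low_count = flag_low,
             flag_cloud_review = flag_cloud)
}
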