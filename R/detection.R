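#' F-beta score
#'
#' Weighted harmonic combination of precision and recall,
#' \deqn{F_\beta = (1+\beta^2)\,\frac{P \times R}{\beta^2 P + R},}
#' with beta < 1 weighting precision over recall. Returns 0 when the
#' denominator is 0 (both precision and recall zero).
#'
#' @param precision,recall values in \[0, 1\].
#' @param beta positive weight; beta = 0.5 doubles the weight on precision,
#'   the setting used when tuning a car detector whose false positives are
#'   costlier than misses.
#' @return The F-beta score in \[0, 1\].
#' @export
#' @examples
#' fbeta_score(0.5578, 0.3032, beta = 0.5)
fbeta_score <- function(precision, recall, beta = 0.5) {
  if (any(precision < 0 | precision > 1, na.rm = TRUE) ||
      any(recall < 0 | recall > 1, na.rm = TRUE))
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  denom <- beta^2 * precision + recall
  out <- ifelse(denom == 0, 0, (1 + beta^2) * precision * recall / denom)
  unname(out)
}

#' Greedy one-to-one matching of detections to ground-truth points
#'
#' Candidate pairs within `max_dist` are accepted in order of increasing
#' distance; each detection and each truth point is used at most once. The
#' default radius of 2.5 m is about half a car length, the natural scale for
#' point detections of cars in very-high-resolution imagery.
#'
#' @param detections data frame with columns `x`, `y`.
#' @param truth data frame with columns `x`, `y`.
#' @param max_dist matching radius in meters.
#' @return Logical vector along `detections`: `TRUE` where matched.
#' @export
match_detections <- function(detections, truth, max_dist = 2.5) {
  nd <- nrow(detections); nt <- nrow(truth)
  matched <- logical(nd)
  if (nd == 0L || nt == 0L) return(matched)
  # candidate pairs via a spatial bucket hash of width max_dist: every pair
  # within max_dist shares a bucket or lies in one of the 8 neighbors
  tb <- split(seq_len(nt), paste(floor(truth$x / max_dist),
                                 floor(truth$y / max_dist)))
  bx <- floor(detections$x / max_dist)
  by <- floor(detections$y / max_dist)
  pi_ <- list(); pj <- list()
  for (dx in -1:1) for (dy in -1:1) {
    hit <- tb[paste(bx + dx, by + dy)]
    len <- lengths(hit)
    if (!sum(len)) next
    key <- paste(dx, dy)
    pi_[[key]] <- rep.int(seq_len(nd), len)
    pj[[key]] <- unlist(hit, use.names = FALSE)
  }
  if (!length(pi_)) return(matched)
  i <- unlist(pi_, use.names = FALSE)
  j <- unlist(pj, use.names = FALSE)
  d <- sqrt((detections$x[i] - truth$x[j])^2 + (detections$y[i] - truth$y[j])^2)
  ok <- d <= max_dist
  if (!any(ok)) return(matched)
  pairs <- cbind(i[ok], j[ok], d[ok])
  pairs <- pairs[order(pairs[, 3L]), , drop = FALSE]
  used_t <- logical(nt)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (!matched[i] && !used_t[j]) {
      matched[i] <- TRUE
      used_t[j] <- TRUE
    }
  }
  matched
}

#' Sweep the detector confidence threshold and score each cut by F-beta
#'
#' For each threshold in `{0, step, 2*step, ..., 1}` the detections with
#' score >= threshold are matched one-to-one to the ground-truth points,
#' precision and recall are computed, and the F-beta score evaluated. The
#' chosen threshold attains the maximum F-beta; among ties the largest
#' threshold is returned (favoring precision).
#'
#' @param detections data frame with `x`, `y`, `score`.
#' @param truth_points data frame with `x`, `y`; must be non-empty.
#' @param beta F-beta weight (default 0.5).
#' @param step threshold step in (0, 1); the default 0.05 gives 21 thresholds.
#' @param max_dist matching radius passed to [match_detections()].
#' @return Object of class `fbeta_sweep`: list with `table` (threshold,
#'   precision, recall, fbeta), `beta`, and `chosen_threshold`.
#' @export
sweep_confidence_threshold <- function(detections, truth_points, beta = 0.5,
                                       step = 0.05, max_dist = 2.5) {
  if (nrow(truth_points) == 0L)
    stop("truth_points is empty: precision/recall are undefined", call. = FALSE)
  if (step <= 0 || step >= 1) stop("step must lie in (0, 1)", call. = FALSE)
  thresholds <- seq(0, 1, by = step)
  if (thresholds[length(thresholds)] < 1) thresholds <- c(thresholds, 1)
  nt <- nrow(truth_points)
  # matching is monotone in the threshold only through the retained set, so
  # recompute the match at every cut
  prec <- rec <- fb <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    keep <- detections[detections$score >= thresholds[k], , drop = FALSE]
    if (nrow(keep) == 0L) {
      prec[k] <- 0; rec[k] <- 0; fb[k] <- 0
      next
    }
    m <- match_detections(keep, truth_points, max_dist)
    tp <- sum(m)
    prec[k] <- tp / nrow(keep)
    rec[k] <- tp / nt
    fb[k] <- fbeta_score(prec[k], rec[k], beta)
  }
  best <- max(fb)
  chosen <- max(thresholds[fb == best])
  structure(list(table = data.frame(threshold = thresholds, precision = prec,
                                    recall = rec, fbeta = fb),
                 beta = beta, chosen_threshold = chosen),
            class = "fbeta_sweep")
}

#' @export
print.fbeta_sweep <- function(x, ...) {
  cat(sprintf("F-beta confidence-threshold sweep (beta = %g, %d thresholds)\n",
              x$beta, nrow(x$table)))
  cat(sprintf("chosen threshold: %.2f (F%g = %.4f)\n", x$chosen_threshold,
              x$beta, max(x$table$fbeta)))
  invisible(x)
}

#' Filter detections by confidence score
#'
#' Keeps exactly the records with `score >= threshold`, preserving order.
#'
#' @param detections data frame with a `score` column.
#' @param threshold confidence cut in \[0, 1\] (default 0.45, the tuned value).
#' @return The surviving rows of `detections`.
#' @export
filter_by_confidence <- function(detections, threshold = 0.45) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  detections[detections$score >= threshold, , drop = FALSE]
}

#' Keep only the processed detector class
#'
#' Only the "small car" class enters the pipeline; other classes are dropped
#' and their count reported as an attribute and a message.
#'
#' @param detections data frame with a `class` column.
#' @param class_label the class to retain.
#' @return Retained rows, with attribute `n_dropped`.
#' @export
filter_class <- function(detections, class_label = "small car") {
  keep <- detections$class == class_label
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("dropped %d detections of other classes", n_dropped))
  out <- detections[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Exclusion layer of land-use polygons
#'
#' A set of planar polygons where cars cannot occur (water bodies, crop
#' fields, forests, parks, runways), each carrying an OpenStreetMap-style
#' key/value tag. Detections falling inside these polygons are treated as
#' false positives.
#'
#' @param polygons list of two-column vertex matrices.
#' @param tags data frame with one row per polygon: `key`, `value`, and
#'   optionally `aoi_id`. Keys are typically among landuse, place, natural,
#'   leisure, aeroway.
#' @return Object of class `exclusion_layer`.
#' @export
exclusion_layer <- function(polygons = list(), tags = NULL) {
  if (is.null(tags))
    tags <- data.frame(key = character(0), value = character(0))
  if (length(polygons) != nrow(tags))
    stop("one tag row per polygon required", call. = FALSE)
  for (i in seq_along(polygons)) {
    ok <- tryCatch(validate_polygon(polygons[[i]]), error = function(e) e)
    if (inherits(ok, "error"))
      stop(sprintf("invalid exclusion polygon %d: %s", i, conditionMessage(ok)),
           call. = FALSE)
  }
  structure(list(polygons = polygons, tags = tags), class = "exclusion_layer")
}

#' @export
print.exclusion_layer <- function(x, ...) {
  cat(sprintf("exclusion layer: %d polygons\n", length(x$polygons)))
  if (nrow(x$tags)) print(table(paste(x$tags$key, x$tags$value, sep = "=")))
  invisible(x)
}

#' Remove detections falling inside exclusion polygons
#'
#' Partitions the detections into those outside every exclusion polygon
#' (kept) and those inside or on the boundary of at least one (removed as
#' false positives). The two parts are disjoint and their union is the input.
#'
#' @param detections data frame with `x`, `y`.
#' @param layer an [exclusion_layer()].
#' @return List with data frames `kept` and `removed`.
#' @export
filter_false_positives <- function(detections, layer) {
  stopifnot(inherits(layer, "exclusion_layer"))
  inside <- rep(FALSE, nrow(detections))
  for (p in layer$polygons) {
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- points_in_polygon(detections$x[todo], detections$y[todo], p)
  }
  list(kept = detections[!inside, , drop = FALSE],
       removed = detections[inside, , drop = FALSE])
}
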