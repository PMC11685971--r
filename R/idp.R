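#' Matching months between the baseline year and comparison years
#'
#' A city can only be compared across years in calendar months observed in
#' both the baseline year and the comparison year (avoiding hidden
#' seasonality). Cities with no matching month for any comparison year are
#' excluded with a reason.
#'
#' @param stats a [monthly_cell_means()] result.
#' @param baseline_year baseline year.
#' @param compare_years vector of comparison years.
#' @return Data frame `aoi_id`, `year`, `month` of matched city-months, with
#'   attribute `excluded`: data frame `aoi_id`, `reason` for dropped cities.
#' @export
match_months <- function(stats, baseline_year = 2019,
                         compare_years = c(2020, 2022)) {
  aois <- sort(unique(stats$aoi_id))
  rows <- list(); excluded <- list()
  for (a in aois) {
    sa <- stats[stats$aoi_id == a, , drop = FALSE]
    base_months <- unique(sa$month[sa$year == baseline_year])
    any_match <- FALSE
    for (y in compare_years) {
      mm <- intersect(base_months, unique(sa$month[sa$year == y]))
      if (length(mm)) {
        any_match <- TRUE
        rows[[paste(a, y)]] <- data.frame(aoi_id = a, year = y,
                                          month = sort(mm))
      }
    }
    if (!any_match)
      excluded[[a]] <- data.frame(
        aoi_id = a,
        reason = "no month observed in both the baseline and any comparison year")
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(aoi_id = character(0), year = integer(0), month = integer(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
  else data.frame(aoi_id = character(0), reason = character(0))
  out
}

#' Pool baseline months into a per-cell baseline table
#'
#' For the baseline year, averages each cell's monthly mean car counts over
#' the months in which the cell was covered, and attaches the cell's baseline
#' population from the analysis grid. Only cells covered in at least one
#' baseline month appear.
#'
#' @param stats a [monthly_cell_means()] result.
#' @param grid a [build_grid()] result (or several AOIs' grids bound together).
#' @param baseline_year baseline year.
#' @return `BaselineCellTable` data frame: `aoi_id`, `cell_id`, `people`
#'   (baseline population), `cars` (pooled mean cars).
#' @export
pool_baseline <- function(stats, grid, baseline_year = 2019) {
  sb <- stats[stats$year == baseline_year, , drop = FALSE]
  if (nrow(sb) == 0L)
    return(data.frame(aoi_id = character(0), cell_id = character(0),
                      people = numeric(0), cars = numeric(0)))
  agg <- stats::aggregate(mean_cars ~ aoi_id + cell_id, data = sb, FUN = mean)
  idx <- match(agg$cell_id, grid$cell_id)
  if (anyNA(idx)) stop("baseline stats reference cells missing from the grid",
                       call. = FALSE)
  data.frame(aoi_id = agg$aoi_id, cell_id = agg$cell_id,
             people = grid$baseline_people[idx], cars = agg$mean_cars)
}

#' Fit the per-cell ratio model
#'
#' The population-to-car ratio r = people/cars is computed for every baseline
#' cell with at least one car; cells with zero cars borrow the global median
#' of the defined ratios. The median's scope is per city by default
#' (car-ownership levels differ across cities); `scope = "global"` pools all
#' cities.
#'
#' @param baseline a [pool_baseline()] table.
#' @param scope `"city"` or `"global"` median for zero-car cells.
#' @return Object of class `ratio_model`: list with `cells` (data frame
#'   `aoi_id`, `cell_id`, `ratio`, `imputed`) and `fallback` (named per-city
#'   vector, or single value for global scope).
#' @export
fit_ratio <- function(baseline, scope = c("city", "global")) {
  scope <- match.arg(scope)
  if (nrow(baseline) == 0L) stop("empty baseline table", call. = FALSE)
  cells <- baseline
  cells$ratio <- NA_real_
  pos <- cells$cars > 0
  cells$ratio[pos] <- cells$people[pos] / cells$cars[pos]
  if (scope == "global") {
    if (!any(pos)) stop("all cells have zero cars; ratio undefined", call. = FALSE)
    fallback <- stats::median(cells$ratio[pos])
    cells$ratio[!pos] <- fallback
  } else {
    fallback <- numeric(0)
    for (a in unique(cells$aoi_id)) {
      ia <- cells$aoi_id == a
      if (!any(ia & pos))
        stop(sprintf("all cells of city '%s' have zero cars; ratio undefined city-wide", a),
             call. = FALSE)
      med <- stats::median(cells$ratio[ia & pos])
      fallback[a] <- med
      cells$ratio[ia & !pos] <- med
    }
  }
  structure(list(cells = data.frame(aoi_id = cells$aoi_id,
                                    cell_id = cells$cell_id,
                                    ratio = cells$ratio, imputed = !pos),
                 fallback = fallback, scope = scope),
            class = "ratio_model")
}

#' Predict population from cars with the ratio model
#'
#' Predicted people = per-cell baseline ratio times the period's mean cars;
#' a cell with zero cars is predicted as zero people (the ratio method's
#' defining lower-bound behavior). Cells without a baseline ratio are
#' excluded with a reported count.
#'
#' @param model a [fit_ratio()] model.
#' @param period_cars data frame `cell_id`, `cars` for the comparison period
#'   (matching cells).
#' @return Data frame `cell_id`, `cars`, `predicted_people`, with attribute
#'   `n_excluded`.
#' @export
predict_ratio <- function(model, period_cars) {
  idx <- match(period_cars$cell_id, model$cells$cell_id)
  n_excluded <- sum(is.na(idx))
  if (n_excluded > 0)
    message(sprintf("excluded %d cells absent from the baseline ratio table",
                    n_excluded))
  keep <- !is.na(idx)
  out <- data.frame(cell_id = period_cars$cell_id[keep],
                    cars = period_cars$cars[keep],
                    predicted_people = model$cells$ratio[idx[keep]] *
                      period_cars$cars[keep])
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Fit the smooth Poisson regression (GAM) of people on cars
#'
#' Penalized cubic-regression-spline Poisson regression with log link,
#' people ~ exp(b0 + f(cars)), fitted by REML through `mgcv`. Pooled monthly
#' means are non-integer, so the quasi-Poisson family (identical score
#' equations, dispersion estimated) is used. Degenerate predictors (constant
#' cars) fall back to an intercept-only fit with a warning. The model records
#' its training range of cars; predictions outside it are flagged rather than
#' silently extrapolated.
#'
#' @param baseline a [pool_baseline()] table for one city.
#' @param k spline basis dimension (default 10).
#' @param min_cells minimum number of cells required (default 10).
#' @param gof_threshold deviance-explained/R-squared level below which the
#'   model is labelled low-confidence (default 0.6).
#' @return Object of class `car_gam`: list with the fitted model, `intercept`,
#'   `x_range`, `n_cells`, `stats` (deviance explained, R-squared, dispersion,
#'   smoothing parameter, effective df), and `low_confidence`.
#' @export
fit_gam <- function(baseline, k = 10, min_cells = 10, gof_threshold = 0.6) {
  df <- data.frame(people = baseline$people, cars = baseline$cars)
  df <- df[is.finite(df$people) & is.finite(df$cars), , drop = FALSE]
  if (nrow(df) < min_cells)
    stop(sprintf("need at least %d cells to fit the regression model (got %d)",
                 min_cells, nrow(df)), call. = FALSE)
  n_unique <- length(unique(df$cars))
  if (n_unique < 3L) {
    warning("car counts are (nearly) constant; falling back to an intercept-only model")
    fit <- stats::glm(people ~ 1, family = stats::quasipoisson(), data = df)
    sm <- summary(fit)
    out <- list(fit = fit, type = "intercept",
                intercept = unname(stats::coef(fit)[1L]),
                x_range = range(df$cars), n_cells = nrow(df),
                stats = list(dev_expl = 0, r_sq = 0,
                             dispersion = sm$dispersion, sp = NA_real_,
                             edf = 1),
                low_confidence = TRUE)
    class(out) <- "car_gam"
    return(out)
  }
  # keep the basis well below saturation: at most one basis function per two
  # cells (never below 4), and no more than the number of unique car values
  k_use <- max(4L, min(k, n_unique, floor(nrow(df) / 2)))
  k_use <- min(k_use, n_unique)
  fit <- mgcv::gam(people ~ s(cars, bs = "cr", k = k_use),
                   family = stats::quasipoisson(), method = "REML", data = df)
  if (!fit$converged)
    stop("smooth Poisson regression did not converge; ",
         sprintf("n = %d cells, %d unique car values, basis dimension %d",
                 nrow(df), n_unique, k_use), call. = FALSE)
  sm <- summary(fit)
  r_sq <- max(sm$r.sq, 0)
  out <- list(fit = fit, type = "gam",
              intercept = unname(stats::coef(fit)[1L]),
              x_range = range(df$cars), n_cells = nrow(df),
              stats = list(dev_expl = sm$dev.expl, r_sq = sm$r.sq,
                           dispersion = sm$dispersion,
                           sp = unname(fit$sp), edf = sum(fit$edf)),
              low_confidence = sm$dev.expl < gof_threshold)
  class(out) <- "car_gam"
  out
}

#' @export
print.car_gam <- function(x, ...) {
  cat(sprintf("smooth Poisson regression of people on cars (%s)\n", x$type))
  cat(sprintf("  n = %d cells, cars in [%.2f, %.2f]\n", x$n_cells,
              x$x_range[1], x$x_range[2]))
  cat(sprintf("  deviance explained = %.1f%%, dispersion = %.2f%s\n",
              100 * x$stats$dev_expl, x$stats$dispersion,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Predict population from cars with the regression model
#'
#' Predicted mean exp(b0 + f(cars)) per cell, with a 95% interval from the
#' smooth's standard error on the link scale. Predictions are strictly
#' positive even at zero cars (the regression method's upper-bound behavior).
#' Cells whose car count lies outside the training range are flagged
#' `out_of_range`.
#'
#' @param model a [fit_gam()] model.
#' @param period_cars data frame `cell_id`, `cars` (matching cells).
#' @return Data frame `cell_id`, `cars`, `predicted_people`, `lwr`, `upr`,
#'   `out_of_range`.
#' @export
predict_gam <- function(model, period_cars) {
  nd <- data.frame(cars = period_cars$cars)
  pr <- stats::predict(model$fit, newdata = nd, type = "link", se.fit = TRUE)
  data.frame(cell_id = period_cars$cell_id, cars = period_cars$cars,
             predicted_people = exp(as.numeric(pr$fit)),
             lwr = exp(as.numeric(pr$fit) - 1.96 * as.numeric(pr$se.fit)),
             upr = exp(as.numeric(pr$fit) + 1.96 * as.numeric(pr$se.fit)),
             out_of_range = period_cars$cars < model$x_range[1] |
               period_cars$cars > model$x_range[2])
}

#' Relative population change at cell and city level
#'
#' Computes percent change of predicted vs baseline population. The city
#' level sums the cell predictions (and cell baselines) over the matching
#' cells, so city predictions are additive in their cells by construction.
#'
#' @param predictions data frame `cell_id`, `predicted_people` (one method,
#'   one period, matching cells only).
#' @param baseline data frame `cell_id`, `people` for the same cells
#'   (e.g. a [pool_baseline()] table).
#' @param level `"city"`, `"cell"`, or `"both"`.
#' @return `ChangeEstimate` data frame: `level`, `cell_id` (`NA` at city
#'   level), `predicted_people`, `baseline_people`, `pct_change`.
#' @export
population_change <- function(predictions, baseline,
                              level = c("both", "city", "cell")) {
  level <- match.arg(level)
  idx <- match(predictions$cell_id, baseline$cell_id)
  if (nrow(predictions) == 0L || all(is.na(idx)))
    stop("no matching cells between predictions and baseline", call. = FALSE)
  keep <- !is.na(idx)
  pred <- predictions[keep, , drop = FALSE]
  base_people <- baseline$people[idx[keep]]
  pc <- function(p, b) ifelse(b > 0, 100 * (p - b) / b, NA_real_)
  out <- list()
  if (level %in% c("both", "cell"))
    out$cell <- data.frame(level = "cell", cell_id = pred$cell_id,
                           predicted_people = pred$predicted_people,
                           baseline_people = base_people,
                           pct_change = pc(pred$predicted_people, base_people))
  if (level %in% c("both", "city")) {
    tp <- sum(pred$predicted_people); tb <- sum(base_people)
    out$city <- data.frame(level = "city", cell_id = NA_character_,
                           predicted_people = tp, baseline_people = tb,
                           pct_change = pc(tp, tb))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' End-to-end displacement estimation for all eligible cities
#'
#' Applies the matching-months rule, pools the baseline, fits both linkage
#' models per city, predicts the population for every matched city-month from
#' that month's mean cars on the matching cells only, and reports city-level
#' change estimates for both methods side by side (the ratio method behaves
#' as a lower-bound-style estimator, the regression method as an upper-bound
#' style one; together they bracket the uncertainty). The per-month area
#' coverage attached to each estimate is the percent of the city's grid cells
#' covered that month.
#'
#' @param stats a [monthly_cell_means()] result (screened images only).
#' @param grid bound [build_grid()] tables for all AOIs.
#' @param baseline_year,compare_years analysis years.
#' @param methods subset of `c("ratio", "gam")`.
#' @param gam_k,gam_min_cells passed to [fit_gam()].
#' @param ratio_scope passed to [fit_ratio()].
#' @return List with `city` (city-month change estimates), `cells`
#'   (cell-level changes), `models` (per-city model summaries), and
#'   `excluded` (cities without matching months).
#' @export
estimate_idp <- function(stats, grid, baseline_year = 2019,
                         compare_years = c(2020, 2022),
                         methods = c("ratio", "gam"), gam_k = 10,
                         gam_min_cells = 10, ratio_scope = "city") {
  matched <- match_months(stats, baseline_year, compare_years)
  baseline <- pool_baseline(stats, grid, baseline_year)
  city_rows <- list(); cell_rows <- list(); models <- list()
  for (a in unique(matched$aoi_id)) {
    base_a <- baseline[baseline$aoi_id == a, , drop = FALSE]
    if (nrow(base_a) == 0L) next
    n_grid <- sum(grid$aoi_id == a)
    fit_r <- if ("ratio" %in% methods)
      tryCatch(fit_ratio(base_a, scope = ratio_scope), error = function(e) e)
    fit_g <- if ("gam" %in% methods)
      tryCatch(fit_gam(base_a, k = gam_k, min_cells = gam_min_cells),
               error = function(e) e)
    models[[a]] <- list(ratio = fit_r, gam = fit_g)
    ma <- matched[matched$aoi_id == a, , drop = FALSE]
    for (r in seq_len(nrow(ma))) {
      y <- ma$year[r]; mth <- ma$month[r]
      per <- stats[stats$aoi_id == a & stats$year == y & stats$month == mth, ,
                   drop = FALSE]
      cells <- intersect(base_a$cell_id, per$cell_id)
      if (!length(cells)) next
      period_cars <- data.frame(cell_id = cells,
                                cars = per$mean_cars[match(cells, per$cell_id)])
      base_match <- base_a[base_a$cell_id %in% cells, , drop = FALSE]
      cov_pct <- 100 * length(unique(per$cell_id)) / n_grid
      for (method in methods) {
        fit <- if (method == "ratio") fit_r else fit_g
        if (inherits(fit, "error") || is.null(fit)) next
        pred <- if (method == "ratio") predict_ratio(fit, period_cars)
        else predict_gam(fit, period_cars)
        ch <- population_change(pred, base_match, level = "both")
        city <- ch[ch$level == "city", , drop = FALSE]
        cell <- ch[ch$level == "cell", , drop = FALSE]
        key <- paste(a, y, mth, method)
        city_rows[[key]] <- data.frame(
          aoi_id = a, year = y, month = mth, method = method,
          predicted_people = city$predicted_people,
          baseline_people = city$baseline_people,
          pct_change = city$pct_change, n_cells = nrow(pred),
          area_coverage_pct = cov_pct)
        cell_rows[[key]] <- cbind(aoi_id = a, year = y, month = mth,
                                  method = method, cell)
      }
    }
  }
  list(city = if (length(city_rows)) do.call(rbind, c(city_rows,
                                                      make.row.names = FALSE))
       else data.frame(),
       cells = if (length(cell_rows)) do.call(rbind, c(cell_rows,
                                                       make.row.names = FALSE))
       else data.frame(),
       models = models,
       excluded = attr(matched, "excluded"))
}
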