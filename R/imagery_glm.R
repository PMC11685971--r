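#' Imagery-feature model of log car density
#'
#' Gaussian linear model of the log car density of each image (detected cars
#' divided by imaged area in km^2, log-transformed) on imagery features:
#' image resolution (categorical, reference level 0.3 m), snow presence
#' (categorical, reference absent), off-nadir angle, sun elevation, and cloud
#' coverage. Zero-detection images have undefined log density and are
#' excluded with a reported count. Covariates without variation are dropped
#' from the design with a warning; a fully collinear design is an error
#' naming the offending columns.
#'
#' @param images image metadata data frame with `n_detections`, `area_km2`,
#'   `gsd_m`, `snow`, `off_nadir_deg`, `sun_elev_deg`, `cloud_frac`, and
#'   optionally `acquired_at` (used by [glm_diagnostics()] for the
#'   independence check).
#' @param min_images minimum number of usable images (default 30).
#' @return Object of class `feature_glm`: list with the `lm` fit, the result
#'   `table` (parameter, estimate, 2.5%, 97.5%, t value, p value; log scale),
#'   `n_excluded_zero`, and `dropped` covariates.
#' @export
fit_feature_glm <- function(images, min_images = 30) {
  req <- c("n_detections", "area_km2", "gsd_m", "snow", "off_nadir_deg",
           "sun_elev_deg", "cloud_frac")
  miss <- setdiff(req, names(images))
  if (length(miss)) stop("images table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dens <- images$n_detections / images$area_km2
  usable <- is.finite(dens) & dens > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0)
    message(sprintf("excluded %d zero-density images (log undefined)", n_excluded))
  img <- images[usable, , drop = FALSE]
  if (nrow(img) < min_images)
    stop(sprintf("need at least %d images with positive density (got %d)",
                 min_images, nrow(img)), call. = FALSE)
  df <- data.frame(
    log_density = log(img$n_detections / img$area_km2),
    resolution = factor(img$gsd_m, levels = sort(unique(img$gsd_m))),
    snow = factor(ifelse(img$snow, "yes", "no"), levels = c("no", "yes")),
    off_nadir = img$off_nadir_deg,
    sun_elev = img$sun_elev_deg,
    cloud = img$cloud_frac)
  covars <- c("resolution", "snow", "off_nadir", "sun_elev", "cloud")
  zero_var <- covars[vapply(covars, function(v) {
    length(unique(df[[v]])) < 2L
  }, logical(1))]
  use <- setdiff(covars, zero_var)
  if (!length(use))
    stop("collinear design: all covariates are constant (",
         paste(zero_var, collapse = ", "), ")", call. = FALSE)
  if (length(zero_var))
    warning("dropping constant covariates: ", paste(zero_var, collapse = ", "))
  fml <- stats::reformulate(use, response = "log_density")
  fit <- stats::lm(fml, data = df)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased))
    stop("collinear design: aliased coefficients for ",
         paste(aliased, collapse = ", "), call. = FALSE)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  labels <- rownames(sm$coefficients)
  pretty <- labels
  pretty[pretty == "(Intercept)"] <- "Intercept"
  pretty <- sub("^resolution", "Image resolution - ", pretty)
  pretty[pretty == "snowyes"] <- "Snow presence - Yes"
  pretty[pretty == "off_nadir"] <- "Off-Nadir"
  pretty[pretty == "sun_elev"] <- "Sun elevation"
  pretty[pretty == "cloud"] <- "Cloud coverage"
  tab <- data.frame(parameter = pretty,
                    estimate = sm$coefficients[, 1],
                    lwr = ci[, 1], upr = ci[, 2],
                    t_value = sm$coefficients[, 3],
                    p_value = sm$coefficients[, 4])
  rownames(tab) <- NULL
  acquired_at <- if ("acquired_at" %in% names(img)) img$acquired_at else NULL
  structure(list(fit = fit, table = tab, n_excluded_zero = n_excluded,
                 dropped = zero_var, acquired_at = acquired_at),
            class = "feature_glm")
}

#' @export
print.feature_glm <- function(x, ...) {
  cat("imagery-feature model of log car density\n")
  print(x$table, digits = 3)
  if (x$n_excluded_zero > 0)
    cat(sprintf("(%d zero-density images excluded)\n", x$n_excluded_zero))
  invisible(x)
}

#' Residual diagnostics for the imagery-feature model
#'
#' Checks the Gaussian model's assumptions: residual normality
#' (Shapiro-Wilk), homoscedasticity (Breusch-Pagan, plus the slope of squared
#' residuals on fitted values as a variance-trend statistic), and
#' independence (lag-1 autocorrelation of residuals ordered by acquisition
#' time, with a Durbin-Watson test).
#'
#' @param result a [fit_feature_glm()] object.
#' @param alpha significance level for the heteroscedasticity flag.
#' @return List with `normality` (W, p), `homoscedasticity` (BP statistic, p,
#'   variance-trend slope and p, `flagged`), `independence` (lag-1 r, DW
#'   statistic, p), and `residual_summary`.
#' @export
glm_diagnostics <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "feature_glm"))
  fit <- result$fit
  res <- stats::residuals(fit)
  fitted <- stats::fitted(fit)
  normality <- if (stats::sd(res) == 0) list(W = 1, p = 1)
  else {
    sw <- stats::shapiro.test(res)
    list(W = unname(sw$statistic), p = sw$p.value)
  }
  if (stats::sd(res) == 0) {
    homo <- list(bp = 0, bp_p = 1, trend_slope = 0, trend_p = 1, flagged = FALSE)
  } else {
    bp <- lmtest::bptest(fit)
    tr <- stats::lm(I(res^2) ~ fitted)
    trs <- summary(tr)$coefficients
    trend_p <- if (nrow(trs) > 1) trs[2, 4] else 1
    homo <- list(bp = unname(bp$statistic), bp_p = bp$p.value,
                 trend_slope = if (nrow(trs) > 1) trs[2, 1] else 0,
                 trend_p = trend_p,
                 flagged = bp$p.value < alpha || trend_p < alpha)
  }
  ord <- if (!is.null(result$acquired_at)) order(result$acquired_at)
  else seq_along(res)
  r_ord <- res[ord]
  lag1 <- if (length(r_ord) > 2 && stats::sd(r_ord) > 0)
    stats::cor(r_ord[-1], r_ord[-length(r_ord)]) else 0
  dw <- if (stats::sd(res) > 0) lmtest::dwtest(fit, order.by = ord)
  else list(statistic = c(DW = 2), p.value = 1)
  list(normality = normality,
       homoscedasticity = homo,
       independence = list(lag1 = lag1, dw = unname(dw$statistic),
                           dw_p = dw$p.value),
       residual_summary = summary(res))
}
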