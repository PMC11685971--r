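stats_row <- function(aoi, cell, year, month, cars) {
  data.frame(aoi_id = aoi, cell_id = cell, year = year, month = month,
             mean_cars = cars, n_images = 1)
}

test_that("matching months are set intersections with exclusion reasons", {
  st <- rbind(stats_row("a", "c", 2019, c(3, 4), 1),
              stats_row("a", "c", 2022, c(4, 7), 1),
              stats_row("b", "c2", 2019, 5, 1),
              stats_row("b", "c2", 2020, 5, 1),
              stats_row("z", "c3", 2019, 1, 1),
              stats_row("z", "c3", 2022, 9, 1))
  m <- match_months(st, 2019, c(2020, 2022))
  expect_equal(m$month[m$aoi_id == "a" & m$year == 2022], 4)
  expect_equal(m$month[m$aoi_id == "b" & m$year == 2020], 5)
  expect_equal(nrow(m[m$aoi_id == "b" & m$year == 2022, ]), 0)
  excl <- attr(m, "excluded")
  expect_equal(excl$aoi_id, "z")
  expect_match(excl$reason, "no month")
})

test_that("baseline pooling averages available months per cell", {
  grid <- data.frame(aoi_id = "a", cell_id = c("c1", "c2"), x0 = 0, y0 = 0,
                     cell_m = 1000, baseline_people = c(100, 200))
  st <- rbind(stats_row("a", "c1", 2019, 4, 2),
              stats_row("a", "c1", 2019, 5, 4),
              stats_row("a", "c2", 2019, 5, 6),
              stats_row("a", "c1", 2022, 4, 1))
  bt <- pool_baseline(st, grid, 2019)
  expect_equal(bt$cars[bt$cell_id == "c1"], 3)
  expect_equal(bt$cars[bt$cell_id == "c2"], 6)
  expect_equal(bt$people, c(100, 200))
  # single baseline month equals that month's stats
  bt1 <- pool_baseline(stats_row("a", "c1", 2019, 4, 2.5), grid, 2019)
  expect_equal(bt1$cars, 2.5)
  # ragged coverage equals per-cell oracle recomputation
  set.seed(41)
  months <- 3:8
  st2 <- do.call(rbind, lapply(1:2, function(i) {
    ms <- sort(sample(months, sample(2:6, 1)))
    stats_row("a", paste0("c", i), 2019, ms, runif(length(ms), 0, 10))
  }))
  bt2 <- pool_baseline(st2, grid, 2019)
  for (i in 1:2) {
    cid <- paste0("c", i)
    expect_equal(bt2$cars[bt2$cell_id == cid],
                 mean(st2$mean_cars[st2$cell_id == cid]))
  }
})

test_that("ratio model computes per-cell ratios with median imputation", {
  bt <- data.frame(aoi_id = "a", cell_id = c("c1", "c2", "c3", "c4"),
                   people = c(10, 8, 50, 30), cars = c(2, 2, 5, 0))
  m <- fit_ratio(bt)
  r <- setNames(m$cells$ratio, m$cells$cell_id)
  expect_equal(unname(r["c1"]), 5)
  expect_equal(unname(r["c2"]), 4)
  expect_equal(unname(r["c3"]), 10)
  # zero-car cell borrows the median of {5, 4, 10}
  expect_equal(unname(r["c4"]), 5)
  expect_true(m$cells$imputed[m$cells$cell_id == "c4"])
  # all-zero people: ratios and fallback are zero
  bt0 <- data.frame(aoi_id = "a", cell_id = c("c1", "c2"), people = 0,
                    cars = c(1, 2))
  m0 <- fit_ratio(bt0)
  expect_true(all(m0$cells$ratio == 0))
  # city with no cars at all is undefined
  btz <- data.frame(aoi_id = "a", cell_id = "c1", people = 5, cars = 0)
  expect_error(fit_ratio(btz), "zero cars")
})

test_that("per-city and global median scopes differ as configured", {
  bt <- rbind(data.frame(aoi_id = "a", cell_id = c("a1", "a2", "a0"),
                         people = c(10, 20, 5), cars = c(1, 2, 0)),
              data.frame(aoi_id = "b", cell_id = c("b1", "b2", "b0"),
                         people = c(100, 120, 5), cars = c(1, 2, 0)))
  per_city <- fit_ratio(bt, scope = "city")
  glob <- fit_ratio(bt, scope = "global")
  ra <- function(m, id) m$cells$ratio[m$cells$cell_id == id]
  expect_equal(ra(per_city, "a0"), 10)       # median(10, 10)
  expect_equal(ra(per_city, "b0"), 80)       # median(100, 60)
  expect_equal(ra(glob, "a0"), median(c(10, 10, 100, 60)))
  expect_equal(ra(glob, "a0"), ra(glob, "b0"))
})

test_that("ratio prediction is exact in a noiseless proportional world", {
  bt <- proportional_baseline(n_cells = 40, k = 50)
  model <- fit_ratio(bt)
  # uniform displacement 0.6
  period <- data.frame(cell_id = bt$cell_id, cars = 0.6 * bt$cars)
  pred <- predict_ratio(model, period)
  expect_equal(sum(pred$predicted_people), 0.6 * sum(bt$people),
               tolerance = 1e-9)
  # arbitrary per-cell displacement field, still exact
  set.seed(15)
  mult <- runif(40, 0, 2)
  period2 <- data.frame(cell_id = bt$cell_id, cars = mult * bt$cars)
  pred2 <- predict_ratio(model, period2)
  expect_equal(pred2$predicted_people, mult * bt$people, tolerance = 1e-9)
  # zero cars everywhere predicts zero people
  pred0 <- predict_ratio(model, data.frame(cell_id = bt$cell_id, cars = 0))
  expect_true(all(pred0$predicted_people == 0))
  # unknown cells are excluded with a count
  expect_message(
    p <- predict_ratio(model, data.frame(cell_id = c("nope", bt$cell_id[1]),
                                         cars = c(1, 1))),
    "excluded 1")
  expect_equal(nrow(p), 1)
})

test_that("a flat population-car relationship is fitted flat", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    bt <- data.frame(aoi_id = "a", cell_id = sprintf("c%d", 1:500),
                     people = rpois(500, 200), cars = runif(500, 0, 100))
    m <- fit_gam(bt)
    xg <- seq(0, 100, length.out = 50)
    p <- predict_gam(m, data.frame(cell_id = sprintf("g%d", 1:50), cars = xg))
    max(abs(p$predicted_people - 200)) / 200
  }, numeric(1))
  expect_lt(median(errs), 0.01)
})

test_that("the smooth recovers a monotone log link under Poisson noise", {
  mare <- vapply(1:20, function(s) {
    set.seed(s)
    cars <- runif(500, 0, 200)
    mu <- exp(1 + 0.8 * log(1 + cars))
    bt <- data.frame(aoi_id = "a", cell_id = sprintf("c%d", 1:500),
                     people = rpois(500, mu), cars = cars)
    m <- fit_gam(bt)
    mean(abs(fitted(m$fit) - mu) / mu)
  }, numeric(1))
  expect_lt(median(mare), 0.10)
})

test_that("fitted means reproduce the training total (Poisson score equation)", {
  set.seed(77)
  cars <- runif(300, 0, 100)
  bt <- data.frame(aoi_id = "a", cell_id = sprintf("c%d", 1:300),
                   people = rpois(300, 3 * cars + 20), cars = cars)
  m <- fit_gam(bt)
  expect_equal(sum(fitted(m$fit)), sum(bt$people),
               tolerance = 0.005)
})

test_that("regression predictions are positive at zero cars and flag extrapolation", {
  set.seed(55)
  cars <- runif(200, 1, 50)
  bt <- data.frame(aoi_id = "a", cell_id = sprintf("c%d", 1:200),
                   people = rpois(200, 10 * cars), cars = cars)
  m <- fit_gam(bt)
  p <- predict_gam(m, data.frame(cell_id = c("z", "big"), cars = c(0, 500)))
  expect_gt(p$predicted_people[1], 0)
  expect_true(all(p$out_of_range))  # 0 below and 500 above the training range
  inr <- predict_gam(m, data.frame(cell_id = "mid", cars = 25))
  expect_false(inr$out_of_range)
  expect_true(inr$lwr < inr$predicted_people & inr$predicted_people < inr$upr)
})

test_that("noiseless monotone worlds are interpolated at training points", {
  cars <- seq(1, 60, length.out = 120)
  people <- exp(2 + 0.9 * log(1 + cars))
  bt <- data.frame(aoi_id = "a", cell_id = sprintf("c%d", 1:120),
                   people = people, cars = cars)
  m <- fit_gam(bt)
  p <- predict_gam(m, data.frame(cell_id = bt$cell_id, cars = bt$cars))
  # prediction at a training value reproduces the model's fit there exactly
  expect_equal(p$predicted_people, unname(fitted(m$fit)), tolerance = 1e-10)
  # and the noiseless fit tracks the curve closely on average (the natural
  # boundary condition of the cubic spline limits pointwise accuracy at the
  # range ends)
  expect_lt(mean(abs(p$predicted_people - people) / people), 0.01)
  expect_gt(m$stats$dev_expl, 0.999)
})

test_that("degenerate car predictors fall back to an intercept-only model", {
  bt <- data.frame(aoi_id = "a", cell_id = sprintf("c%d", 1:30),
                   people = rep(c(90, 110), 15), cars = 5)
  expect_warning(m <- fit_gam(bt), "constant")
  expect_equal(m$type, "intercept")
  p <- predict_gam(m, data.frame(cell_id = "c1", cars = 5))
  expect_equal(p$predicted_people, 100, tolerance = 1e-6)
  expect_error(fit_gam(bt[1:5, ]), "at least 10")
})

test_that("population change is additive and matches direct percents", {
  bt <- data.frame(aoi_id = "a", cell_id = c("c1", "c2"),
                   people = c(4000, 6000), cars = c(10, 20))
  pred <- data.frame(cell_id = c("c1", "c2"), predicted_people = c(400, 800))
  ch <- population_change(pred, bt)
  city <- ch[ch$level == "city", ]
  expect_equal(city$predicted_people,
               sum(ch$predicted_people[ch$level == "cell"]))
  expect_equal(city$pct_change, 100 * (1200 - 10000) / 10000)  # -88%
  cell <- ch[ch$level == "cell", ]
  expect_equal(cell$pct_change, c(-90, 100 * (800 - 6000) / 6000))
  # unchanged prediction gives 0% at both levels
  same <- data.frame(cell_id = c("c1", "c2"),
                     predicted_people = c(4000, 6000))
  expect_true(all(population_change(same, bt)$pct_change == 0))
  expect_error(population_change(data.frame(cell_id = "zz",
                                            predicted_people = 1), bt),
               "matching")
})

test_that("regression damps displacement relative to the ratio method", {
  gam_milder <- vapply(1:20, function(s) {
    set.seed(s)
    people <- rlnorm(500, log(300), 0.9)
    cars <- rpois(500, 0.04 * people)
    bt <- data.frame(aoi_id = "a", cell_id = sprintf("c%d", 1:500),
                     people = people, cars = cars)
    # emptied-cell scenario: half the cells lose everyone
    mult <- rep(c(0, 1), length.out = 500)
    period <- data.frame(cell_id = bt$cell_id,
                         cars = rpois(500, 0.04 * mult * people))
    rm <- fit_ratio(bt)
    gm <- fit_gam(bt)
    b <- sum(bt$people)
    ratio_ch <- abs(100 * (sum(predict_ratio(rm, period)$predicted_people) - b) / b)
    gam_ch <- abs(100 * (sum(predict_gam(gm, period)$predicted_people) - b) / b)
    gam_ch <= ratio_ch
  }, logical(1))
  expect_gt(mean(gam_milder), 0.5)
})

test_that("end-to-end estimation returns bracketed city estimates", {
  cfg <- small_world_config(seed = 12)
  w <- generate_world(cfg)
  grids <- do.call(rbind, lapply(w$aois, build_grid, pop_cells = w$pop))
  counts <- list()
  for (i in seq_len(nrow(w$images))) {
    iid <- w$images$image_id[i]
    det <- w$detections[w$detections$image_id == iid &
                          w$detections$class == "small car", ]
    g <- grids[grids$aoi_id == w$images$aoi_id[i], ]
    cc <- suppressMessages(count_cars_per_cell(det, g, w$footprints[[iid]]))
    cc$image_id <- iid
    counts[[iid]] <- cc
  }
  st <- monthly_cell_means(do.call(rbind, counts), w$images)
  est <- estimate_idp(st, grids, 2019, c(2020, 2022), gam_min_cells = 5)
  expect_true(all(c("ratio", "gam") %in% est$city$method))
  expect_true(all(est$city$area_coverage_pct >= 0 &
                    est$city$area_coverage_pct <= 100))
  # city rows equal the sum of their cell rows, exactly
  for (r in seq_len(min(nrow(est$city), 10))) {
    cr <- est$city[r, ]
    cells <- est$cells[est$cells$aoi_id == cr$aoi_id &
                         est$cells$year == cr$year &
                         est$cells$month == cr$month &
                         est$cells$method == cr$method, ]
    expect_equal(cr$predicted_people, sum(cells$predicted_people))
  }
  # the displacement sign is recovered for the war year at city level
  war <- est$city[est$city$year == 2022, ]
  east <- war[war$aoi_id == "city01", ]
  west <- war[war$aoi_id == "city02", ]
  expect_true(all(east$pct_change < 0))
  expect_true(all(west$pct_change > 0))
})
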