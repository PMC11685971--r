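aligned_aoi <- function(size_m = 3000, x0 = 0, y0 = 0, id = "a") {
  list(aoi_id = id, oblast = "East", poly = rect_poly(x0, y0, x0 + size_m,
                                                      y0 + size_m))
}

fine_cells <- function(aoi, cell_m = 100, people_fun = function(n) rep(5, n)) {
  bb <- poly_bbox(aoi$poly)
  g <- expand.grid(x = seq(bb[1] + cell_m / 2, bb[3], by = cell_m),
                   y = seq(bb[2] + cell_m / 2, bb[4], by = cell_m))
  data.frame(aoi_id = aoi$aoi_id, x = g$x, y = g$y, cell_m = cell_m,
             people = people_fun(nrow(g)))
}

test_that("grid construction tiles aligned AOIs exactly and conserves people", {
  aoi <- aligned_aoi(3000)
  cells <- fine_cells(aoi, people_fun = function(n) runif(n, 0, 20))
  g <- build_grid(aoi, cells)
  expect_equal(nrow(g), 9)
  expect_equal(sum(g$baseline_people), sum(cells$people), tolerance = 1e-6)
  # identical geometry across repeated builds (determinism)
  expect_identical(g$cell_id, build_grid(aoi, cells)$cell_id)
  # sub-cell AOI snaps into a single cell
  small <- list(aoi_id = "s", oblast = "East",
                poly = rect_poly(1000, 1000, 1400, 1500))
  sc <- data.frame(aoi_id = "s", x = 1200, y = 1250, cell_m = 100, people = 7)
  expect_equal(nrow(build_grid(small, sc)), 1)
})

test_that("per-cell counts use half-open intervals and conserve totals", {
  aoi <- aligned_aoi(3000)
  g <- build_grid(aoi, fine_cells(aoi))
  fp <- aoi$poly
  set.seed(13)
  det <- data.frame(x = runif(100, 0, 3000), y = runif(100, 0, 3000))
  cc <- count_cars_per_cell(det, g, fp)
  expect_equal(sum(cc$n_cars), 100)
  # independent double-loop assignment
  brute <- setNames(rep(0, nrow(g)), g$cell_id)
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(nrow(g))) {
      if (det$x[i] >= g$x0[j] && det$x[i] < g$x0[j] + 1000 &&
          det$y[i] >= g$y0[j] && det$y[i] < g$y0[j] + 1000)
        brute[g$cell_id[j]] <- brute[g$cell_id[j]] + 1
    }
  }
  expect_equal(setNames(cc$n_cars, cc$cell_id), brute)
  # edge point goes to the right/upper cell, counted once
  edge <- data.frame(x = 1000, y = 500)
  ce <- count_cars_per_cell(edge, g, fp)
  expect_equal(sum(ce$n_cars), 1)
  expect_equal(ce$cell_id[ce$n_cars == 1], "a_E1_N0")
  # detections outside the grid are dropped with a count
  expect_message(
    out <- count_cars_per_cell(data.frame(x = -50, y = 50), g, fp),
    "outside")
  expect_equal(attr(out, "n_outside"), 1)
  expect_equal(sum(out$n_cars), 0)
})

test_that("cell coverage honors the 50% footprint rule", {
  aoi <- aligned_aoi(2000)
  g <- build_grid(aoi, fine_cells(aoi))
  # footprint covering the left 40% of the two left cells
  cc <- count_cars_per_cell(data.frame(x = numeric(0), y = numeric(0)), g,
                            rect_poly(0, 0, 400, 2000))
  cov <- setNames(cc$covered, cc$cell_id)
  expect_false(any(cov[c("a_E0_N0", "a_E0_N1")]))
  # 60% coverage counts
  cc2 <- count_cars_per_cell(data.frame(x = numeric(0), y = numeric(0)), g,
                             rect_poly(0, 0, 600, 2000))
  cov2 <- setNames(cc2$covered, cc2$cell_id)
  expect_true(all(cov2[c("a_E0_N0", "a_E0_N1")]))
  expect_false(any(cov2[c("a_E1_N0", "a_E1_N1")]))
})

month_stats_fixture <- function() {
  images <- data.frame(image_id = c("i1", "i2", "i3"), aoi_id = "a",
                       year = c(2019, 2019, 2019), month = c(4, 4, 5))
  counts <- rbind(
    data.frame(image_id = "i1", cell_id = c("c1", "c2"), n_cars = c(4, 8),
               covered = TRUE),
    data.frame(image_id = "i2", cell_id = c("c1", "c2"), n_cars = c(6, 1),
               covered = c(TRUE, FALSE)),
    data.frame(image_id = "i3", cell_id = c("c1", "c2"), n_cars = c(3, 2),
               covered = TRUE))
  list(images = images, counts = counts)
}

test_that("monthly means average only covering images", {
  fx <- month_stats_fixture()
  st <- monthly_cell_means(fx$counts, fx$images)
  get <- function(cell, m) st$mean_cars[st$cell_id == cell & st$month == m]
  expect_equal(get("c1", 4), 5)       # (4 + 6) / 2
  expect_equal(get("c2", 4), 8)       # i2 does not cover c2
  expect_equal(get("c1", 5), 3)       # single image month
  expect_equal(st$n_images[st$cell_id == "c1" & st$month == 4], 2)
  # uncovered cell-months are absent, not zero
  expect_false(any(st$mean_cars == 0 & st$n_images == 0))
})

test_that("ragged coverage means equal a brute-force recomputation", {
  set.seed(29)
  images <- data.frame(image_id = sprintf("i%d", 1:12), aoi_id = "a",
                       year = 2019, month = sample(4:6, 12, replace = TRUE))
  counts <- do.call(rbind, lapply(images$image_id, function(id)
    data.frame(image_id = id, cell_id = sprintf("c%d", 1:5),
               n_cars = rpois(5, 6), covered = runif(5) < 0.7)))
  st <- monthly_cell_means(counts, images)
  for (r in seq_len(nrow(st))) {
    imgs <- images$image_id[images$month == st$month[r]]
    sub <- counts[counts$image_id %in% imgs & counts$cell_id == st$cell_id[r] &
                    counts$covered, ]
    expect_equal(st$mean_cars[r], mean(sub$n_cars))
    expect_equal(st$n_images[r], nrow(sub))
  }
})

density_stats <- function(baseline, target, year = 2022) {
  # one covered 1 km cell per city-month; mean_cars equals density
  rbind(
    do.call(rbind, lapply(names(baseline), function(a)
      data.frame(aoi_id = a, cell_id = paste0(a, "_c"), year = 2019, month = 5,
                 mean_cars = baseline[[a]], n_images = 1))),
    do.call(rbind, lapply(names(target), function(a)
      data.frame(aoi_id = a, cell_id = paste0(a, "_c"), year = year, month = 5,
                 mean_cars = target[[a]], n_images = 1))))
}

test_that("relative density change reproduces hand-computed anchors", {
  st <- density_stats(list(a = 10), list(a = 10))
  ch <- relative_density_change(st, 2019, 2022, level = "aoi")
  expect_equal(ch$pct_change, 0)
  st2 <- density_stats(list(a = 10), list(a = 2))
  expect_equal(relative_density_change(st2, 2019, 2022, "aoi")$pct_change, -80)
  # two-city oblast: average densities first, then the change
  st3 <- density_stats(list(A = 2, B = 6), list(A = 4, B = 3))
  ch3 <- relative_density_change(st3, 2019, 2022, level = "oblast",
                                 oblasts = c(A = "obl", B = "obl"))
  expect_equal(ch3$pct_change, 100 * (3.5 - 4) / 4)
  # scale invariance
  st4 <- st3
  st4$mean_cars <- st4$mean_cars * 37
  ch4 <- relative_density_change(st4, 2019, 2022, level = "oblast",
                                 oblasts = c(A = "obl", B = "obl"))
  expect_equal(ch4$pct_change, ch3$pct_change)
})

test_that("units lacking data report missing, never zero", {
  st <- density_stats(list(a = 10), list(b = 5))
  ch <- relative_density_change(st, 2019, 2022, level = "aoi")
  expect_true(all(is.na(ch$pct_change)))
  expect_true(all(grepl("missing", ch$reason)))
  st0 <- density_stats(list(a = 0), list(a = 5))
  ch0 <- relative_density_change(st0, 2019, 2022, level = "aoi")
  expect_true(is.na(ch0$pct_change))
  expect_match(ch0$reason, "zero")
})

test_that("quarterly changes group target months by calendar quarter", {
  st <- rbind(
    data.frame(aoi_id = "a", cell_id = "c", year = 2019,
               month = c(2, 5), mean_cars = c(10, 10), n_images = 1),
    data.frame(aoi_id = "a", cell_id = "c", year = 2022,
               month = c(2, 5), mean_cars = c(5, 20), n_images = 1))
  ch <- relative_density_change(st, 2019, 2022, level = "aoi",
                                period = "quarter")
  expect_equal(sort(ch$period), c("2022Q1", "2022Q2"))
  expect_equal(ch$pct_change[ch$period == "2022Q1"], -50)
  expect_equal(ch$pct_change[ch$period == "2022Q2"], 100)
})

test_that("East-drop/West-rise worlds recover the correct change signs", {
  hits <- 0L; total <- 0L
  for (s in 1:25) {
    cfg <- small_world_config(seed = 100 + s)
    cfg$image_model$months <- 5
    cfg$image_model$per_month_lambda <- 2
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
    oblasts <- setNames(vapply(w$aois, `[[`, "", "oblast"),
                        vapply(w$aois, `[[`, "", "aoi_id"))
    ch <- relative_density_change(st, 2019, 2022, level = "oblast",
                                  oblasts = oblasts)
    truth_sign <- c(East = -1, West = 1)
    for (r in seq_len(nrow(ch))) {
      if (is.na(ch$pct_change[r])) next
      total <- total + 1L
      if (sign(ch$pct_change[r]) == truth_sign[[ch$unit[r]]])
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
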