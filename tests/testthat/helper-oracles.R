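# Independent oracles, deliberately coded with different algorithms than the
# package implementations they check.

# even-odd ray-casting point-in-polygon (package uses winding number)
oracle_point_in_polygon <- function(px, py, poly) {
  if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  on_segment <- function(x, y, x1, y1, x2, y2) {
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    cr == 0 && x >= min(x1, x2) && x <= max(x1, x2) &&
      y >= min(y1, y2) && y <= max(y1, y2)
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    j <- n
    inside <- FALSE
    for (i in seq_len(n)) {
      if (on_segment(x, y, xs[i], ys[i], xs[j], ys[j])) return(TRUE)
      if ((ys[i] > y) != (ys[j] > y)) {
        xint <- xs[i] + (y - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# quadratic greedy detection-truth matcher (package uses a bucket hash)
oracle_match <- function(det, truth, max_dist = 2.5) {
  nd <- nrow(det); nt <- nrow(truth)
  matched <- logical(nd); used <- logical(nt)
  if (nd == 0 || nt == 0) return(matched)
  d <- outer(seq_len(nd), seq_len(nt), function(i, j)
    sqrt((det$x[i] - truth$x[j])^2 + (det$y[i] - truth$y[j])^2))
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[m[1], m[2]] > max_dist) break
    matched[m[1]] <- TRUE; used[m[2]] <- TRUE
    d[m[1], ] <- Inf; d[, m[2]] <- Inf
    if (all(matched) || all(used)) break
  }
  matched
}

# precision/recall/F-beta per threshold by direct enumeration
oracle_sweep <- function(det, truth, beta, step, max_dist = 2.5) {
  taus <- seq(0, 1, by = step)
  fb <- vapply(taus, function(tau) {
    keep <- det[det$score >= tau, , drop = FALSE]
    if (nrow(keep) == 0) return(0)
    tp <- sum(oracle_match(keep, truth, max_dist))
    p <- tp / nrow(keep); r <- tp / nrow(truth)
    if (beta^2 * p + r == 0) 0 else (1 + beta^2) * p * r / (beta^2 * p + r)
  }, numeric(1))
  list(taus = taus, fbeta = fb, argmax = max(taus[fb == max(fb)]))
}

# area-weighted people under a rectangle footprint, summed cell by cell
oracle_people_under_rect <- function(cells, xmin, ymin, xmax, ymax) {
  total <- 0
  for (i in seq_len(nrow(cells))) {
    h <- cells$cell_m[i] / 2
    ox <- max(0, min(cells$x[i] + h, xmax) - max(cells$x[i] - h, xmin))
    oy <- max(0, min(cells$y[i] + h, ymax) - max(cells$y[i] - h, ymin))
    total <- total + cells$people[i] * (ox * oy) / cells$cell_m[i]^2
  }
  total
}

# random simple (star-shaped) polygon around a center
random_simple_polygon <- function(cx, cy, r_range = c(20, 80), n = 7) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_range[1], r_range[2])
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}
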