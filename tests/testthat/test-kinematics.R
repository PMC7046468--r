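## CASA kinematics closed forms, oracle checks and invariants.

test_that("path smoothing: identity window, collinear invariance, damping", {
  tr <- make_straight_track(n = 10)
  expect_equal(smooth_path(tr, 1), tr[, .(x_um, y_um)])
  ## equally spaced collinear points are invariant under the moving average
  sm <- smooth_path(tr, 5)
  expect_equal(sm$x_um, tr$x_um, tolerance = 1e-12)
  expect_equal(sm$y_um, tr$y_um, tolerance = 1e-12)
  ## a square-wave zig-zag is strictly damped
  zz <- data.table::data.table(x_um = as.numeric(1:20),
                               y_um = rep(c(2, -2), 10))
  smz <- smooth_path(zz, 3)
  expect_lt(max(abs(smz$y_um[3:18])), 2)
  expect_error(smooth_path(tr, 4), "odd")
  ## matches the independently coded oracle
  set.seed(9)
  v <- rnorm(17)
  w <- data.table::data.table(x_um = v, y_um = rev(v))
  expect_equal(smooth_path(w, 5)$x_um, oracle_smooth(v, 5), tolerance = 1e-12)
})

test_that("straight and stationary tracks give their closed-form kinematics", {
  tr <- make_straight_track(speed = 100)
  k <- compute_kinematics(tr)
  expect_equal(k$vcl, 100, tolerance = 1e-12)
  expect_equal(k$vsl, 100, tolerance = 1e-12)
  expect_equal(k$vap, 100, tolerance = 1e-12)
  expect_equal(k$str_pct, 100, tolerance = 1e-12)
  expect_equal(k$lin_pct, 100, tolerance = 1e-12)
  expect_equal(k$duration, 23 / 48, tolerance = 1e-12)

  still <- make_straight_track(speed = 0)
  ks <- compute_kinematics(still)
  expect_equal(ks$vcl, 0)
  expect_equal(ks$str_pct, 0)  # 0/0 convention
  expect_equal(classify_track(ks), "IM")
})

test_that("kinematics of a beating swimmer match a brute-force polyline oracle", {
  dt <- 1 / 48
  t <- (0:23) * dt
  x <- 50 * t
  y <- 2 * sin(2 * pi * 14 * t)
  tr <- data.table::data.table(track_id = 1L, frame = 0:23, x_um = x, y_um = y)
  k <- compute_kinematics(tr, window = 5, frame_interval = dt)
  dur <- 23 * dt
  expect_equal(k$vcl, oracle_path_length(x, y) / dur, tolerance = 1e-9)
  expect_equal(k$vsl, sqrt((x[24] - x[1])^2 + (y[24] - y[1])^2) / dur,
               tolerance = 1e-9)
  xs <- oracle_smooth(x, 5)
  ys <- oracle_smooth(y, 5)
  expect_equal(k$vap, oracle_path_length(xs, ys) / dur, tolerance = 1e-9)
  expect_true(k$vcl > k$vap && k$vap > k$vsl)
})

test_that("WHO classification applies the strict threshold rules", {
  thr <- class_thresholds()
  row <- function(vap, str, vsl) list(vap = vap, str_pct = str, vsl = vsl)
  expect_equal(classify_track(row(30, 85, 20), thr), "PM")
  expect_equal(classify_track(row(10, 40, 5), thr), "NPM")   # vap > 5
  expect_equal(classify_track(row(3, 50, 12), thr), "NPM")   # vsl > 11
  expect_equal(classify_track(row(3, 50, 2), thr), "IM")
  ## strict inequality at the PM boundary falls through to NPM
  expect_equal(classify_track(row(25, 90, 20), thr), "NPM")
  ## PM takes precedence even when NPM conditions also hold
  expect_equal(classify_track(row(40, 95, 35), thr), "PM")
})

test_that("kinematics are scale-equivariant and time-reversal invariant", {
  set.seed(14)
  for (case in 1:8) {
    n <- sample(12:30, 1)
    tr <- data.table::data.table(track_id = 1L, frame = 0:(n - 1),
                                 x_um = cumsum(rnorm(n, 1, 2)),
                                 y_um = cumsum(rnorm(n, 0, 2)))
    k <- compute_kinematics(tr, frame_interval = 1 / 48)
    k3 <- compute_kinematics(
      data.table::data.table(track_id = 1L, frame = tr$frame,
                             x_um = 3 * tr$x_um, y_um = 3 * tr$y_um),
      frame_interval = 1 / 48)
    expect_equal(k3$vcl, 3 * k$vcl, tolerance = 1e-9)
    expect_equal(k3$vsl, 3 * k$vsl, tolerance = 1e-9)
    expect_equal(k3$vap, 3 * k$vap, tolerance = 1e-9)
    expect_equal(k3$str_pct, k$str_pct, tolerance = 1e-9)
    expect_equal(k3$lin_pct, k$lin_pct, tolerance = 1e-9)
    rev_tr <- data.table::data.table(track_id = 1L, frame = tr$frame,
                                     x_um = rev(tr$x_um), y_um = rev(tr$y_um))
    kr <- compute_kinematics(rev_tr, frame_interval = 1 / 48)
    expect_equal(kr$vcl, k$vcl, tolerance = 1e-9)
    expect_equal(kr$vsl, k$vsl, tolerance = 1e-9)
    ## the chord is the shortest path and smoothing contracts the path
    expect_gte(k$vcl, k$vap - 1e-12)
    expect_gte(k$vcl, k$vsl - 1e-12)
  }
})

test_that("short tracks are excluded with a reason, not an error", {
  tr <- make_straight_track(n = 6)
  k <- compute_kinematics(tr, min_points = 12)
  expect_false(k$included)
  expect_equal(k$reason, "below_min_track_length")
  expect_equal(k$vcl, 100, tolerance = 1e-9)  # still computed
})

test_that("well summaries aggregate medians, fractions and flags", {
  s <- data.table::data.table(
    vcl = c(10, 20, 90, 50), vsl = 1, vap = 1, str_pct = 1, lin_pct = 1,
    n_points = 24, duration = 0.5, included = c(TRUE, TRUE, TRUE, FALSE),
    class = c("PM", "NPM", "IM", NA))
  w <- summarize_well(s[included == TRUE], well = "A01")
  expect_equal(w$median_vcl, 20)
  s2 <- data.table::data.table(included = rep(TRUE, 4),
                               class = c("PM", "PM", "NPM", "IM"),
                               vcl = c(100, 110, 30, 5))
  w2 <- summarize_well(s2)
  expect_equal(c(w2$pm_pct, w2$npm_pct, w2$im_pct), c(50, 25, 25))
  w3 <- summarize_well(s[0])
  expect_equal(w3$n_tracks, 0)
  expect_true(grepl("low_count", w3$flags))
  expect_true(is.na(w3$median_vcl))
})

test_that("well PM fraction reflects the generator's class proportions", {
  cfg <- motility_sim_config(n_cells_per_class = c(pm = 300, npm = 100, im = 100))
  fld <- simulate_field(cfg, seed = 77)
  fld$tracks[, well := "A01"]
  w <- well_motility_table(fld$tracks, frame_interval = cfg$frame_interval)
  ## 60% generated PM; binomial 3 SD at n = 500 is ~6.6 points, plus a small
  ## one-sided loss from edge-reflected swimmers
  expect_lt(abs(w$pm_pct - 60), 8)
  expect_equal(w$n_tracks, 500)
})
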