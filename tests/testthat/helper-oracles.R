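## Independent oracles and fixture builders used across the suite. These are
## deliberately written with a different style (plain loops, no shared code
## with the package internals) so they can serve as cross-checks.

## Polyline length by explicit loop.
oracle_path_length <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  total
}

## Centred moving average with shrinking edge windows, by explicit loop.
oracle_smooth <- function(v, window) {
  h <- (window - 1) / 2
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1, n - i)
    out[i] <- mean(v[(i - hh):(i + hh)])
  }
  out
}

## Exhaustive minimal-cost frame-to-frame assignment for small instances:
## every mapping of heads to distinct candidate detections (or to nothing)
## is enumerated. Cost = sum of squared link distances + maxd^2 per
## unmatched head and per unmatched detection. Returns the minimal cost.
oracle_assignment_cost <- function(heads, dets, maxd) {
  n_h <- nrow(heads)
  n_d <- nrow(dets)
  maxd2 <- maxd^2
  best <- Inf
  recurse <- function(h, used, acc) {
    if (h > n_h) {
      cost <- acc + maxd2 * sum(!used)
      if (cost < best) best <<- cost
      return(invisible())
    }
    ## null option
    recurse(h + 1, used, acc + maxd2)
    for (d in seq_len(n_d)) {
      if (!used[d]) {
        d2 <- (heads[h, 1] - dets[d, 1])^2 + (heads[h, 2] - dets[d, 2])^2
        if (d2 <= maxd2) {
          used[d] <- TRUE
          recurse(h + 1, used, acc + d2)
          used[d] <- FALSE
        }
      }
    }
    invisible()
  }
  if (n_d == 0) return(maxd2 * n_h)
  recurse(1, logical(n_d), 0)
  best
}

## Total linking cost realised by a set of tracks over consecutive frame
## pairs, in the same objective as above.
realized_linking_cost <- function(detections, tracks, maxd) {
  maxd2 <- maxd^2
  frames <- sort(unique(detections$frame))
  total <- 0
  for (k in seq_len(length(frames) - 1)) {
    f0 <- frames[k]; f1 <- frames[k + 1]
    n0 <- sum(detections$frame == f0)
    n1 <- sum(detections$frame == f1)
    links <- 0
    for (id in unique(tracks$track_id)) {
      tt <- tracks[tracks$track_id == id, ]
      a <- tt[tt$frame == f0, ]
      b <- tt[tt$frame == f1, ]
      if (nrow(a) == 1 && nrow(b) == 1) {
        total <- total + (a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2
        links <- links + 1
      }
    }
    total <- total + maxd2 * ((n0 - links) + (n1 - links))
  }
  total
}

## Straight constant-velocity track fixture.
make_straight_track <- function(n = 24, speed = 100, dt = 1 / 48,
                                theta = 0.3, x0 = 100, y0 = 100) {
  t <- (0:(n - 1)) * dt
  out <- data.table::data.table(
    track_id = 1L, frame = 0:(n - 1),
    x_um = x0 + speed * t * cos(theta),
    y_um = y0 + speed * t * sin(theta)
  )
  data.table::setattr(out, "frame_interval", dt)
  out
}

## Match detected tracks to ground-truth tracks by mean distance over shared
## frames; returns recall over ground truth and the RMSE (um) of matched
## point pairs.
track_recall_rmse <- function(found, truth, match_tol_um = 3) {
  matched_gt <- character(0)
  sq_err <- numeric(0)
  gt_split <- split(truth, truth$track_id)
  for (id in unique(found$track_id)) {
    tt <- found[found$track_id == id, ]
    best_gt <- NA
    best_d <- Inf
    for (g in names(gt_split)) {
      gg <- gt_split[[g]]
      shared <- intersect(tt$frame, gg$frame)
      if (length(shared) < 2) next
      a <- tt[match(shared, tt$frame), ]
      b <- gg[match(shared, gg$frame), ]
      d <- mean(sqrt((a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2))
      if (d < best_d) { best_d <- d; best_gt <- g }
    }
    if (!is.na(best_gt) && best_d < match_tol_um) {
      matched_gt <- union(matched_gt, best_gt)
      gg <- gt_split[[best_gt]]
      shared <- intersect(tt$frame, gg$frame)
      a <- tt[match(shared, tt$frame), ]
      b <- gg[match(shared, gg$frame), ]
      sq_err <- c(sq_err, (a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2)
    }
  }
  list(recall = length(matched_gt) / length(gt_split),
       rmse_um = sqrt(mean(sq_err)))
}
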