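## Ground-truthed simulation of 2-D sperm swimming tracks.

## Fold coordinates into [0, L] by reflection at the field edges.
.reflect_into <- function(x, L) {
  if (L <= 0) stop("field size must be > 0")
  period <- 2 * L
  x <- x %% period
  ifelse(x > L, period - x, x)
}

## Batch generator: n tracks of one class as two n x n_frames matrices.
## Motion models: PM = straight drift at a sampled speed plus a sinusoidal
## lateral (flagellar-beat) oscillation; NPM = AR(1)-correlated jitter around
## a slowly drifting centre; IM = isotropic iid Gaussian jitter. All tracks
## are reflected at the field edges so every point stays in-field.
.simulate_class_tracks <- function(n, class_label, config) {
  nf <- config$n_frames
  t <- (seq_len(nf) - 1) * config$frame_interval
  fx <- config$field_size_um[1]
  fy <- config$field_size_um[2]
  if (n == 0L) {
    return(list(x = matrix(numeric(0), 0L, nf), y = matrix(numeric(0), 0L, nf)))
  }
  x0 <- runif(n, 0, fx)
  y0 <- runif(n, 0, fy)
  if (class_label == "PM") {
    speed <- pmax(rnorm(n, config$pm_speed_mean, config$pm_speed_sd), 1)
    theta <- runif(n, 0, 2 * pi)
    phase <- runif(n, 0, 2 * pi)
    beat <- config$pm_beat_amplitude_um *
      sin(outer(rep(2 * pi * config$pm_beat_frequency_hz, n), t) +
            matrix(phase, n, nf))
    drift <- outer(speed, t)
    x <- matrix(x0, n, nf) + drift * cos(theta) - beat * sin(theta)
    y <- matrix(y0, n, nf) + drift * sin(theta) + beat * cos(theta)
  } else if (class_label == "NPM") {
    theta <- runif(n, 0, 2 * pi)
    drift <- outer(rep(config$npm_drift_speed, n), t)
    rho <- config$npm_jitter_corr
    sig <- config$npm_jitter_scale_um
    ox <- matrix(0, n, nf)
    oy <- matrix(0, n, nf)
    ox[, 1] <- rnorm(n, 0, sig)
    oy[, 1] <- rnorm(n, 0, sig)
    innov_sd <- sig * sqrt(1 - rho^2)
    for (j in 2:nf) {
      ox[, j] <- rho * ox[, j - 1] + rnorm(n, 0, innov_sd)
      oy[, j] <- rho * oy[, j - 1] + rnorm(n, 0, innov_sd)
    }
    x <- matrix(x0, n, nf) + drift * cos(theta) + ox
    y <- matrix(y0, n, nf) + drift * sin(theta) + oy
  } else if (class_label == "IM") {
    sig <- config$im_jitter_scale_um
    x <- matrix(x0, n, nf) + matrix(rnorm(n * nf, 0, sig), n, nf)
    y <- matrix(y0, n, nf) + matrix(rnorm(n * nf, 0, sig), n, nf)
  } else {
    stop("unknown class label: ", class_label)
  }
  list(x = .reflect_into(x, fx), y = .reflect_into(y, fy))
}

#' Simulate a single sperm swimming track
#'
#' @param class_label One of `"PM"`, `"NPM"`, `"IM"`.
#' @param config A [motility_sim_config()].
#' @param seed Optional integer seed for this track.
#'
#' @return A `data.table` with columns `track_id`, `frame` (0-based), `x_um`,
#'   `y_um`, carrying `frame_interval` as an attribute.
#' @export
simulate_track <- function(class_label, config = motility_sim_config(),
                           seed = config$seed) {
  validate_motility_sim_config(config)
  class_label <- match.arg(toupper(class_label), c("PM", "NPM", "IM"))
  if (!is.null(seed)) set.seed(seed)
  m <- .simulate_class_tracks(1L, class_label, config)
  out <- data.table(
    track_id = 1L,
    frame = 0:(config$n_frames - 1L),
    x_um = as.numeric(m$x[1L, ]),
    y_um = as.numeric(m$y[1L, ])
  )
  setattr(out, "frame_interval", config$frame_interval)
  out[]
}

#' Simulate one imaging field of swimming tracks with ground truth
#'
#' Generates `n_cells_per_class` tracks of each kinematic class, uniformly
#' seeded over the field. Deterministic given `seed`.
#'
#' @param config A [motility_sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#'
#' @return A list with `tracks` (long `data.table`: `track_id`, `frame`,
#'   `x_um`, `y_um`) and `truth` (`data.table`: `track_id`, `true_class`).
#' @export
simulate_field <- function(config = motility_sim_config(), seed = config$seed) {
  validate_motility_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  counts <- config$n_cells_per_class
  labels <- c("PM", "NPM", "IM")
  nf <- config$n_frames
  pieces <- vector("list", 3L)
  truths <- vector("list", 3L)
  next_id <- 0L
  for (k in seq_along(labels)) {
    n <- counts[[k]]
    m <- .simulate_class_tracks(n, labels[k], config)
    if (n > 0L) {
      ids <- next_id + seq_len(n)
      pieces[[k]] <- data.table(
        track_id = rep(ids, each = nf),
        frame = rep(0:(nf - 1L), times = n),
        x_um = as.numeric(t(m$x)),
        y_um = as.numeric(t(m$y))
      )
      truths[[k]] <- data.table(track_id = ids, true_class = labels[k])
      next_id <- next_id + n
    }
  }
  tracks <- rbindlist(pieces)
  if (nrow(tracks) == 0L) {
    tracks <- data.table(track_id = integer(), frame = integer(),
                         x_um = numeric(), y_um = numeric())
  }
  truth <- rbindlist(truths)
  if (nrow(truth) == 0L) {
    truth <- data.table(track_id = integer(), true_class = character())
  }
  setattr(tracks, "frame_interval", config$frame_interval)
  list(tracks = tracks[], truth = truth[])
}
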