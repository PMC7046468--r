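## CASA kinematic parameters and WHO motility classification.
##
## VCL (curvilinear velocity) = point-to-point path length / duration;
## VSL (straight-line velocity) = first-to-last chord / duration;
## VAP (average-path velocity) = length of the moving-average-smoothed path
## / duration; STR = 100*VSL/VAP; LIN = 100*VSL/VCL.

#' WHO motility class thresholds
#'
#' Progressively motile (PM): VAP > 25 um/s AND STR > 80%. Non-progressively
#' motile (NPM): VAP > 5 um/s OR VSL > 11 um/s. Otherwise immotile (IM).
#' All inequalities are strict; PM is evaluated first.
#'
#' @param pm_vap_min,pm_str_min,npm_vap_min,npm_vsl_min Threshold values.
#' @return A list of class `class_thresholds`.
#' @export
class_thresholds <- function(pm_vap_min = 25, pm_str_min = 80,
                             npm_vap_min = 5, npm_vsl_min = 11) {
  stopifnot(pm_vap_min > npm_vap_min)
  structure(list(pm_vap_min = pm_vap_min, pm_str_min = pm_str_min,
                 npm_vap_min = npm_vap_min, npm_vsl_min = npm_vsl_min),
            class = "class_thresholds")
}

## Centred moving average with symmetrically shrinking windows at the edges:
## at position i of n the half-width is min(h, i-1, n-i).
.smooth_vec <- function(x, h) {
  n <- length(x)
  if (h == 0L || n <= 2L) return(x)
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + hh + 1L] - cs[i - hh]) / (2L * hh + 1L)
}

#' Smooth a track with a centred moving average
#'
#' Used to construct the average path underlying VAP. The window shrinks
#' symmetrically at the track ends so output length equals input length;
#' `window = 1` is the identity.
#'
#' @param track Track table with `x_um`, `y_um` (one track, ordered).
#' @param window Odd window length in frames.
#'
#' @return A `data.table` with smoothed `x_um`, `y_um`.
#' @export
smooth_path <- function(track, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  track <- as.data.table(track)
  if (nrow(track) < 2L) stop("track must have at least 2 points")
  h <- window %/% 2L
  data.table(x_um = .smooth_vec(track$x_um, h),
             y_um = .smooth_vec(track$y_um, h))
}

## Per-group kinematics kernel. x, y ordered by frame.
.kin_one <- function(x, y, frame_interval, h) {
  n <- length(x)
  duration <- (n - 1) * frame_interval
  vcl <- sum(sqrt(diff(x)^2 + diff(y)^2)) / duration
  vsl <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2) / duration
  xs <- .smooth_vec(x, h)
  ys <- .smooth_vec(y, h)
  vap <- sum(sqrt(diff(xs)^2 + diff(ys)^2)) / duration
  list(vcl = vcl, vsl = vsl, vap = vap,
       str_pct = if (vap > 0) 100 * vsl / vap else 0,
       lin_pct = if (vcl > 0) 100 * vsl / vcl else 0,
       n_points = n, duration = duration)
}

#' Compute CASA kinematics for one track
#'
#' @param track Track table (`frame`, `x_um`, `y_um`) for a single track.
#' @param window Odd moving-average window (frames) for the average path.
#' @param frame_interval Seconds between frames (defaults to the track's
#'   `frame_interval` attribute, else 1/48 s).
#' @param min_points Minimum number of points for inclusion; shorter tracks
#'   are returned with `included = FALSE` and a reason, not an error.
#'
#' @return A one-row `data.table`: `vcl`, `vsl`, `vap`, `str_pct`,
#'   `lin_pct`, `n_points`, `duration`, `included`, `reason`.
#' @export
compute_kinematics <- function(track, window = 5L,
                               frame_interval = NULL, min_points = 12L) {
  track <- as.data.table(track)
  if (is.null(frame_interval)) {
    frame_interval <- attr(track, "frame_interval")
    if (is.null(frame_interval)) frame_interval <- 1 / 48
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- nrow(track)
  if (n < 2L) {
    return(data.table(vcl = NA_real_, vsl = NA_real_, vap = NA_real_,
                      str_pct = NA_real_, lin_pct = NA_real_,
                      n_points = n, duration = NA_real_,
                      included = FALSE, reason = "fewer_than_2_points"))
  }
  if ("frame" %in% names(track)) setorder(track, frame)
  k <- .kin_one(track$x_um, track$y_um, frame_interval, window %/% 2L)
  ok <- n >= min_points
  data.table(vcl = k$vcl, vsl = k$vsl, vap = k$vap, str_pct = k$str_pct,
             lin_pct = k$lin_pct, n_points = n, duration = k$duration,
             included = ok,
             reason = if (ok) NA_character_ else "below_min_track_length")
}

#' Compute kinematics for every track in a long table
#'
#' Vectorised over tracks; grouping columns beyond `track_id` (e.g. `well`,
#' `position`) are carried through.
#'
#' @param tracks Long track table (`track_id`, `frame`, `x_um`, `y_um`,
#'   optional extra grouping columns).
#' @param window,frame_interval,min_points As in [compute_kinematics()].
#' @param thresholds A [class_thresholds()]; the WHO class is appended.
#' @param by Grouping columns identifying a track.
#'
#' @return A `data.table` with one row per track: grouping columns,
#'   kinematic parameters, `included`, and `class` (`PM|NPM|IM`, `NA` for
#'   excluded tracks).
#' @export
track_kinematics <- function(tracks, window = 5L, frame_interval = NULL,
                             min_points = 12L,
                             thresholds = class_thresholds(),
                             by = intersect(c("well", "position", "track_id"),
                                            names(tracks))) {
  tracks <- as.data.table(tracks)
  if (is.null(frame_interval)) {
    frame_interval <- attr(tracks, "frame_interval")
    if (is.null(frame_interval)) frame_interval <- 1 / 48
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  h <- window %/% 2L
  if (nrow(tracks) == 0L) {
    return(data.table(track_id = integer(), vcl = numeric(), vsl = numeric(),
                      vap = numeric(), str_pct = numeric(), lin_pct = numeric(),
                      n_points = integer(), duration = numeric(),
                      included = logical(), class = character()))
  }
  setorderv(tracks, c(by, "frame"))
  kin <- tracks[, .kin_one(x_um, y_um, frame_interval, h), by = by]
  kin[, included := n_points >= min_points]
  kin[, class := fifelse(included,
                         classify_kinematics(vap, str_pct, vsl, thresholds),
                         NA_character_)]
  kin[]
}

#' Classify kinematics into WHO motility classes (vectorised)
#'
#' @param vap,str_pct,vsl Kinematic parameter vectors.
#' @param thresholds A [class_thresholds()].
#' @return Character vector of `"PM"`, `"NPM"`, `"IM"`.
#' @export
classify_kinematics <- function(vap, str_pct, vsl,
                                thresholds = class_thresholds()) {
  fifelse(vap > thresholds$pm_vap_min & str_pct > thresholds$pm_str_min, "PM",
          fifelse(vap > thresholds$npm_vap_min | vsl > thresholds$npm_vsl_min,
                  "NPM", "IM"))
}

#' Classify a single kinematic summary
#'
#' @param summary One-row summary as from [compute_kinematics()].
#' @param thresholds A [class_thresholds()].
#' @return `"PM"`, `"NPM"` or `"IM"`.
#' @export
classify_track <- function(summary, thresholds = class_thresholds()) {
  classify_kinematics(summary$vap, summary$str_pct, summary$vsl, thresholds)
}

#' Aggregate per-track kinematics into a well-level motility result
#'
#' @param summaries Per-track kinematics (rows of [track_kinematics()]) for
#'   one well; excluded tracks are ignored for the median and the class
#'   fractions but still counted in `n_detected`.
#' @param flags Character QC flags for the well (e.g. `"autofocus_error"`,
#'   `"sticky_compound"`); `"low_count"` is added when no track qualifies.
#' @param well Well identifier carried through.
#'
#' @return A one-row `data.table`: `well`, `n_tracks`, `n_detected`,
#'   `median_vcl`, `pm_pct`, `npm_pct`, `im_pct`, `flags`
#'   (semicolon-separated).
#' @export
summarize_well <- function(summaries, flags = character(), well = NA_character_) {
  summaries <- as.data.table(summaries)
  inc <- summaries[included == TRUE]
  n <- nrow(inc)
  if (n == 0L) flags <- union(flags, "low_count")
  frac <- function(cl) if (n > 0L) 100 * sum(inc$class == cl) / n else NA_real_
  data.table(
    well = well,
    n_tracks = n,
    n_detected = nrow(summaries),
    median_vcl = if (n > 0L) median(inc$vcl) else NA_real_,
    pm_pct = frac("PM"), npm_pct = frac("NPM"), im_pct = frac("IM"),
    flags = paste(flags, collapse = ";")
  )
}

#' Per-well motility table for a multi-well track set
#'
#' @param tracks Long track table with a `well` column (and optionally
#'   `position`), as produced by [simulate_plate()] or the tracking stage.
#' @param well_flags Optional `data.frame(well, flag)` of per-well QC flags.
#' @inheritParams track_kinematics
#'
#' @return A `data.table` with one [summarize_well()] row per well.
#' @export
well_motility_table <- function(tracks, window = 5L, frame_interval = NULL,
                                min_points = 12L,
                                thresholds = class_thresholds(),
                                well_flags = NULL) {
  kin <- track_kinematics(tracks, window = window,
                          frame_interval = frame_interval,
                          min_points = min_points, thresholds = thresholds)
  stopifnot("well" %in% names(kin))
  flag_for <- function(w) {
    if (is.null(well_flags)) return(character())
    as.character(well_flags$flag[well_flags$well == w])
  }
  res <- rbindlist(lapply(split(kin, by = "well"), function(d) {
    summarize_well(d, flags = flag_for(d$well[1L]), well = d$well[1L])
  }))
  setorder(res, well)
  res[]
}
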