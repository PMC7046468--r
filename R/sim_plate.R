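## Whole-plate simulation: tracks + flow events + ground truth per well.

## Counter-based seed split: each well's RNG stream is seeded from the root
## seed and the well's fixed grid index, so wells are independent and the
## result does not depend on the order wells are simulated in.
.well_seed <- function(root_seed, well_index, stream = 0L) {
  as.integer((as.double(root_seed) %% 2147483647 * 48271 +
                well_index * 7919 + stream * 104729) %% 2147483647)
}

.truncnorm1 <- function(mean, sd, lo, hi) {
  min(max(rnorm(1L, mean, sd), lo), hi)
}

#' Simulate a full screening plate
#'
#' Generates, for every non-empty well of the layout, `n_positions` imaging
#' fields of swimming tracks and one flow-cytometry event table, applying
#' per-well effects as described in [plate_sim_config()]. DMSO wells always
#' use `motility_scale = 1` and `ar_induction = 0`; pristimerin wells draw a
#' strong motility reduction; A23187 wells use the configured AR induction;
#' compound wells use their entries in `config$effects` (default: no
#' effect). Fully reproducible from `config$seed`.
#'
#' @param config A [plate_sim_config()].
#'
#' @return A list of class `plate_bundle`: `layout`, `effects` (per-well
#'   true effect parameters incl. the biological `well_factor`), `tracks`
#'   (long table with `well`, `position`, `track_id`, `frame`, `x_um`,
#'   `y_um`), `track_truth`, `events` (`well`, `FL1_A`, `FL3_A`),
#'   `event_truth`, plus the configs used.
#' @export
simulate_plate <- function(config = plate_sim_config()) {
  validate_plate_sim_config(config)
  layout <- as.data.table(config$layout)
  ncols <- max(layout$col_idx)
  eff_in <- if (is.null(config$effects)) NULL else as.data.table(config$effects)

  eff_rows <- vector("list", nrow(layout))
  track_rows <- vector("list", nrow(layout))
  truth_rows <- vector("list", nrow(layout))
  event_rows <- vector("list", nrow(layout))
  etruth_rows <- vector("list", nrow(layout))

  for (i in seq_len(nrow(layout))) {
    w <- layout$well[i]
    role <- layout$role[i]
    if (role == "empty") next
    idx <- (layout$row_idx[i] - 1L) * ncols + layout$col_idx[i]
    set.seed(.well_seed(config$seed, idx, stream = 0L))

    well_factor <- exp(rnorm(1L, 0, config$well_effect_sd))
    if (role == "dmso") {
      scale <- 1; ar <- 0
    } else if (role == "pristimerin") {
      scale <- .truncnorm1(config$pristimerin_scale_mean,
                           config$pristimerin_scale_sd, 0.02, 0.8)
      ar <- 0
    } else if (role == "a23187") {
      scale <- 1; ar <- config$a23187_ar_induction
    } else {
      scale <- 1; ar <- 0
      if (!is.null(eff_in)) {
        j <- match(w, eff_in$well)
        if (!is.na(j)) {
          scale <- eff_in$motility_scale[j]
          ar <- eff_in$ar_induction[j]
        }
      }
    }
    eff_rows[[i]] <- data.table(well = w, role = role,
                                motility_scale = scale, ar_induction = ar,
                                well_factor = well_factor)

    mcfg <- scale_motility_config(config$motility_config, scale * well_factor)
    pos_tracks <- vector("list", config$n_positions)
    pos_truth <- vector("list", config$n_positions)
    for (p in seq_len(config$n_positions)) {
      fld <- simulate_field(mcfg, seed = .well_seed(config$seed, idx, stream = p))
      tr <- fld$tracks
      th <- fld$truth
      tr[, position := p]
      th[, position := p]
      pos_tracks[[p]] <- tr
      pos_truth[[p]] <- th
    }
    tr <- rbindlist(pos_tracks)
    th <- rbindlist(pos_truth)
    tr[, well := w]
    th[, well := w]
    track_rows[[i]] <- tr
    truth_rows[[i]] <- th

    fcfg <- config$flow_config
    p4 <- fcfg$proportions
    shift <- min(ar, p4[["pi_neg_pna_neg"]])
    p4[["pi_neg_pna_pos"]] <- p4[["pi_neg_pna_pos"]] + shift
    p4[["pi_neg_pna_neg"]] <- p4[["pi_neg_pna_neg"]] - shift
    fcfg$proportions <- p4
    fw <- simulate_flow_well(fcfg, seed = .well_seed(config$seed, idx, stream = 900L))
    ev <- fw$events
    et <- fw$truth
    ev[, well := w]
    et[, well := w]
    event_rows[[i]] <- ev
    etruth_rows[[i]] <- et
  }

  tracks <- rbindlist(track_rows)
  setcolorder(tracks, c("well", "position", "track_id", "frame", "x_um", "y_um"))
  events <- rbindlist(event_rows)
  setcolorder(events, c("well", "FL1_A", "FL3_A"))
  out <- list(
    layout = layout,
    effects = rbindlist(eff_rows),
    tracks = tracks[],
    track_truth = rbindlist(truth_rows)[],
    events = events[],
    event_truth = rbindlist(etruth_rows)[],
    motility_config = config$motility_config,
    flow_config = config$flow_config,
    frame_interval = config$motility_config$frame_interval,
    seed = config$seed
  )
  class(out) <- "plate_bundle"
  out
}

#' @export
print.plate_bundle <- function(x, ...) {
  cat(sprintf("<plate_bundle: %d wells, %d tracks, %d flow events, seed %d>\n",
              nrow(x$effects), uniqueN(x$tracks[, .(well, position, track_id)]),
              nrow(x$events), x$seed))
  invisible(x)
}

#' Simulate plate-reader and no-dye triage measurements
#'
#' Emulates the two orthogonal interference assays used to triage
#' acrosome-reaction hits: a fluorescence plate read (488 nm excitation,
#' 520 nm and 670 nm emission) that exposes intrinsically fluorescent
#' compounds, and a no-dye replicate whose pseudo live-reacted percentage
#' exposes compounds whose fluorescence mimics a true positive.
#'
#' @param layout A [plate_layout()].
#' @param autofluorescent_wells Wells given a strongly elevated reader
#'   signal (on both emission wavelengths).
#' @param dye_independent_wells Wells whose no-dye replicate still shows a
#'   high pseudo live-reacted percentage.
#' @param baseline_520,baseline_670 Median reader signals of clean wells.
#' @param reader_cv Lognormal CV of the reader signals.
#' @param interference_factor Signal multiplier for autofluorescent wells.
#' @param nodye_baseline_pct,nodye_interference_pct Pseudo-positive
#'   percentages for clean and dye-independent wells.
#' @param seed Integer seed.
#'
#' @return A `data.table` with `well`, `reader_520`, `reader_670`,
#'   `nodye_pct_live_reacted`.
#' @export
simulate_triage_records <- function(layout,
                                    autofluorescent_wells = character(),
                                    dye_independent_wells = character(),
                                    baseline_520 = 1000, baseline_670 = 400,
                                    reader_cv = 0.05,
                                    interference_factor = 8,
                                    nodye_baseline_pct = 1,
                                    nodye_interference_pct = 40,
                                    seed = 1L) {
  validate_plate_layout(layout)
  set.seed(as.integer(seed))
  wells <- layout$well[layout$role != "empty"]
  n <- length(wells)
  rec <- data.table(
    well = wells,
    reader_520 = baseline_520 * exp(rnorm(n, 0, reader_cv)),
    reader_670 = baseline_670 * exp(rnorm(n, 0, reader_cv)),
    nodye_pct_live_reacted = pmax(nodye_baseline_pct * exp(rnorm(n, 0, 0.3)), 0)
  )
  af <- rec$well %in% autofluorescent_wells
  rec[af, `:=`(reader_520 = reader_520 * interference_factor,
               reader_670 = reader_670 * interference_factor)]
  di <- rec$well %in% dye_independent_wells
  rec[di, nodye_pct_live_reacted := nodye_interference_pct * exp(rnorm(sum(di), 0, 0.1))]
  rec[]
}
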