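## Quadrant gating of Pi/PNA flow-cytometry events, acrosome-reaction hit
## calling, event-count QC and fluorescence-interference triage.

#' Derive quadrant gate thresholds from pooled control wells
#'
#' For each channel, a kernel-density estimate (Silverman's rule, on log10
#' intensity) of the pooled DMSO-well events is scanned for modes; the
#' threshold is placed at the deepest valley between the two largest modes.
#' If the density is unimodal the 99.5th percentile of the (single) mode is
#' used instead and the fallback is flagged. Thresholds are returned on the
#' linear fluorescence scale.
#'
#' @param control_events One event table or a list of them (columns `FL1_A`,
#'   `FL3_A`); events are pooled.
#' @param method `"density_valley"` (default) or `"percentile"` (forces the
#'   percentile rule).
#' @param min_events Minimum pooled events required (default 1000).
#' @param mode_min_height Peaks smaller than this fraction of the tallest
#'   are not counted as modes.
#'
#' @return A list of class `gate_thresholds`: `fl1_cut`, `fl3_cut` (linear
#'   scale), per-channel `method` tags, and `fallback` flags.
#' @export
derive_gates <- function(control_events, method = c("density_valley", "percentile"),
                         min_events = 1000L, mode_min_height = 0.05) {
  method <- match.arg(method)
  if (is.data.frame(control_events)) control_events <- list(control_events)
  pooled <- rbindlist(lapply(control_events, function(e) {
    as.data.table(e)[, .(FL1_A, FL3_A)]
  }))
  if (nrow(pooled) < min_events) {
    stop("plate gating failure: fewer than ", min_events, " pooled control events")
  }
  one <- function(v) {
    v <- log10(v[v > 0])
    if (method == "percentile") {
      return(list(cut = 10^quantile(v, 0.995, names = FALSE),
                  method = "percentile", fallback = FALSE))
    }
    d <- density(v, bw = "nrd0")
    y <- d$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1L
    peaks <- peaks[y[peaks] >= mode_min_height * max(y)]
    if (length(peaks) < 2L) {
      return(list(cut = 10^quantile(v, 0.995, names = FALSE),
                  method = "percentile", fallback = TRUE))
    }
    top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
    lo <- min(top2)
    hi <- max(top2)
    valley <- lo + which.min(y[lo:hi]) - 1L
    ## a genuine second mode must be separated by a pronounced valley;
    ## shoulder wiggles of a unimodal cloud are not modes
    if (y[valley] > 0.5 * min(y[top2])) {
      return(list(cut = 10^quantile(v, 0.995, names = FALSE),
                  method = "percentile", fallback = TRUE))
    }
    list(cut = 10^d$x[valley], method = "density_valley", fallback = FALSE)
  }
  g1 <- one(pooled$FL1_A)
  g3 <- one(pooled$FL3_A)
  structure(list(fl1_cut = g1$cut, fl3_cut = g3$cut,
                 method = c(fl1 = g1$method, fl3 = g3$method),
                 fallback = c(fl1 = g1$fallback, fl3 = g3$fallback)),
            class = "gate_thresholds")
}

#' Gate events into Pi/PNA quadrants
#'
#' An event is PNA+ iff `FL1_A > fl1_cut` and Pi+ iff `FL3_A > fl3_cut`
#' (strict inequalities; boundary events are negative).
#'
#' @param event_table Table with `FL1_A`, `FL3_A` columns.
#' @param thresholds A [derive_gates()] result, or a list with `fl1_cut`,
#'   `fl3_cut`.
#'
#' @return A named list of class `quadrant_counts`: counts per population
#'   (in [quadrant_populations()] order) and `total`.
#' @export
gate_events <- function(event_table, thresholds) {
  stopifnot(thresholds$fl1_cut > 0, thresholds$fl3_cut > 0)
  ev <- as.data.table(event_table)
  if (nrow(ev) > 0L && !all(is.finite(ev$FL1_A) & is.finite(ev$FL3_A))) {
    stop("event intensities must be finite")
  }
  pna <- ev$FL1_A > thresholds$fl1_cut
  pi_ <- ev$FL3_A > thresholds$fl3_cut
  counts <- c(
    pi_neg_pna_neg = sum(!pi_ & !pna),
    pi_pos_pna_neg = sum(pi_ & !pna),
    pi_pos_pna_pos = sum(pi_ & pna),
    pi_neg_pna_pos = sum(!pi_ & pna)
  )
  structure(c(as.list(counts), list(total = nrow(ev))),
            class = "quadrant_counts")
}

#' Per-well acrosome-reaction result with QC
#'
#' Computes percent events per quadrant (normalised to total well events)
#' and applies the exclusion rules: wells with fewer than `min_events`
#' events, or with a Pi-positive fraction (dead + dead-reacted) below
#' `min_pi_pos_frac`, are flagged and excluded from hit calling.
#'
#' @param counts A [gate_events()] result.
#' @param well Well identifier.
#' @param min_events Event-count floor (default 200).
#' @param min_pi_pos_frac Minimum Pi+ fraction of events (default 0.02).
#'
#' @return A one-row `data.table`: `well`, `total_events`, `pct_*` per
#'   quadrant, `flags`, `excluded`.
#' @export
ar_well_result <- function(counts, well = NA_character_, min_events = 200L,
                           min_pi_pos_frac = 0.02) {
  stopifnot(inherits(counts, "quadrant_counts") || is.list(counts))
  pops <- quadrant_populations()
  n <- counts$total
  flags <- character()
  if (n < min_events) flags <- c(flags, "low_events")
  pct <- if (n > 0L) {
    vapply(pops, function(p) 100 * counts[[p]] / n, numeric(1L))
  } else {
    setNames(rep(NA_real_, 4L), pops)
  }
  if (n > 0L) {
    pi_pos <- (counts$pi_pos_pna_neg + counts$pi_pos_pna_pos) / n
    if (pi_pos < min_pi_pos_frac) flags <- c(flags, "low_pi_positive")
  }
  out <- data.table(well = well, total_events = n)
  for (p in pops) out[[paste0("pct_", p)]] <- pct[[p]]
  out$flags <- paste(flags, collapse = ";")
  out$excluded <- length(flags) > 0L
  out[]
}

#' Call acrosome-reaction hits
#'
#' A compound well is an AR hit when its live acrosome-reacted (Pi-PNA+)
#' percentage strictly exceeds `induction_threshold_pct` (the maximum
#' induction level reached by the A23187 positive control). QC-excluded
#' wells and control wells are never called.
#'
#' @param ar_results Per-well table with `well`, `pct_pi_neg_pna_pos`,
#'   `excluded`, and a `role` column (join the layout first, or pass
#'   `layout`).
#' @param layout Optional [plate_layout()] to supply roles.
#' @param induction_threshold_pct Hit threshold (default 15).
#'
#' @return The table with a `call` column (`ar_hit|none`, `NA` for
#'   controls/excluded).
#' @export
call_ar_hits <- function(ar_results, layout = NULL,
                         induction_threshold_pct = 15) {
  res <- as.data.table(ar_results)
  if (!is.null(layout)) {
    lay <- as.data.table(layout)[, .(well, role, compound_id)]
    res <- lay[res, on = "well"]
  }
  stopifnot("role" %in% names(res))
  if (!"excluded" %in% names(res)) res[, excluded := FALSE]
  res[, call := NA_character_]
  callable <- res$role == "compound" & !res$excluded
  res[callable,
      call := fifelse(pct_pi_neg_pna_pos > induction_threshold_pct,
                      "ar_hit", "none")]
  res[]
}

#' Triage acrosome-reaction hits for fluorescence interference
#'
#' Two orthogonal checks against the primary hit list: a hit is flagged
#' `autofluorescent` when its 520 nm or 670 nm plate-reader signal exceeds
#' the plate median by more than 3 MAD (robust outlier rule over all
#' triaged wells), and `dye_independent` when its no-dye replicate still
#' shows a pseudo live-reacted percentage above the hit threshold. Hits
#' without a triage record are retained but marked `untriaged`.
#'
#' @param hits Hit table from [call_ar_hits()] (rows with `call == "ar_hit"`
#'   are triaged; other rows pass through unchanged).
#' @param triage_records `data.frame(well, reader_520, reader_670,
#'   nodye_pct_live_reacted)` as from [simulate_triage_records()].
#' @param induction_threshold_pct The AR hit threshold (default 15).
#' @param mad_mult Robust outlier multiplier (default 3).
#'
#' @return The hit table with `interference_flags` and `surviving_hit`
#'   columns; surviving hits are unflagged hits.
#' @export
triage_ar_hits <- function(hits, triage_records,
                           induction_threshold_pct = 15, mad_mult = 3) {
  res <- as.data.table(hits)
  rec <- as.data.table(triage_records)
  med520 <- median(rec$reader_520)
  mad520 <- mad(rec$reader_520)
  med670 <- median(rec$reader_670)
  mad670 <- mad(rec$reader_670)
  res[, interference_flags := NA_character_]
  res[, surviving_hit := FALSE]
  for (i in which(res$call == "ar_hit")) {
    j <- match(res$well[i], rec$well)
    if (is.na(j)) {
      res$interference_flags[i] <- "untriaged"
      res$surviving_hit[i] <- TRUE
      next
    }
    fl <- character()
    if (rec$reader_520[j] > med520 + mad_mult * mad520 ||
        rec$reader_670[j] > med670 + mad_mult * mad670) {
      fl <- c(fl, "autofluorescent")
    }
    if (rec$nodye_pct_live_reacted[j] > induction_threshold_pct) {
      fl <- c(fl, "dye_independent")
    }
    res$interference_flags[i] <- paste(fl, collapse = ";")
    res$surviving_hit[i] <- length(fl) == 0L
  }
  res[]
}

#' Full acrosome-reaction analysis of one plate
#'
#' Derives gates from the pooled DMSO wells, gates every well, applies the
#' event-count QC and calls AR hits.
#'
#' @param events Long event table (`well`, `FL1_A`, `FL3_A`).
#' @param layout A [plate_layout()].
#' @param induction_threshold_pct AR hit threshold (default 15).
#' @param min_events,min_pi_pos_frac QC settings, see [ar_well_result()].
#'
#' @return A list of class `plate_ar_result`: `results` (per-well table with
#'   quadrant percentages and calls), `gates`, `excluded`.
#' @export
analyze_plate_ar <- function(events, layout, induction_threshold_pct = 15,
                             min_events = 200L, min_pi_pos_frac = 0.02) {
  validate_plate_layout(layout)
  events <- as.data.table(events)
  lay <- as.data.table(layout)
  dmso_wells <- lay[role == "dmso", well]
  gates <- derive_gates(events[well %in% dmso_wells])
  res <- rbindlist(lapply(split(events, by = "well"), function(ev) {
    ar_well_result(gate_events(ev, gates), well = ev$well[1L],
                   min_events = min_events, min_pi_pos_frac = min_pi_pos_frac)
  }))
  ## wells with zero events never appear in `events`; report them excluded
  missing <- setdiff(lay[role != "empty", well], res$well)
  if (length(missing) > 0L) {
    res <- rbind(res, rbindlist(lapply(missing, function(w) {
      ar_well_result(structure(list(pi_neg_pna_neg = 0L, pi_pos_pna_neg = 0L,
                                    pi_pos_pna_pos = 0L, pi_neg_pna_pos = 0L,
                                    total = 0L), class = "quadrant_counts"),
                     well = w, min_events = min_events)
    })))
  }
  res <- call_ar_hits(res, layout = lay,
                      induction_threshold_pct = induction_threshold_pct)
  setorder(res, well)
  out <- list(results = res[], gates = gates,
              excluded = res[excluded == TRUE, .(well, flags)])
  class(out) <- "plate_ar_result"
  out
}

#' @export
print.plate_ar_result <- function(x, ...) {
  cat(sprintf("<plate_ar_result: %d wells, %d AR hits, %d excluded, gates FL1 %.3g / FL3 %.3g>\n",
              nrow(x$results), sum(x$results$call == "ar_hit", na.rm = TRUE),
              nrow(x$excluded), x$gates$fl1_cut, x$gates$fl3_cut))
  invisible(x)
}
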