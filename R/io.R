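## File readers and writers: track/event/plate-map CSV schemas, multi-page
## TIFF stacks and the structured run configuration.

.check_cols <- function(d, need, what, path) {
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop(sprintf("%s '%s' is missing columns: %s (found: %s)",
                 what, path, paste(miss, collapse = ", "),
                 paste(names(d), collapse = ", ")))
  }
}

#' Read and write track tables
#'
#' Canonical CSV schema: `track_id`, `frame` (0-based), `x_um`, `y_um`,
#' optionally preceded by `well` and `position` — identical for simulated
#' ground-truth tracks and tracking output.
#'
#' @param tracks Track table.
#' @param path CSV path.
#'
#' @return `read_tracks()` returns a `data.table`; `write_tracks()` the path,
#'   invisibly.
#' @export
write_tracks <- function(tracks, path) {
  fwrite(as.data.table(tracks), path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  d <- fread(path)
  .check_cols(d, c("track_id", "frame", "x_um", "y_um"), "track file", path)
  d
}

#' Read and write flow-cytometry event tables
#'
#' CSV schema: `FL1_A` (PNA-488) and `FL3_A` (propidium iodide), optionally
#' a `well` column. Files ending in `.fcs` are read with the built-in FCS
#' 3.0/3.1 reader ([read_fcs()]). `channel_map` renames instrument channel
#' names (e.g. `FL1-A`) onto the canonical ones.
#'
#' @param events Event table.
#' @param path File path (`.csv` or `.fcs`).
#' @param channel_map Named character vector mapping canonical names
#'   (`FL1_A`, `FL3_A`) to source column names.
#'
#' @return `read_events()` returns a `data.table` with canonical columns.
#' @export
write_events <- function(events, path) {
  fwrite(as.data.table(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, channel_map = c(FL1_A = "FL1_A", FL3_A = "FL3_A")) {
  d <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    read_fcs(path)
  } else {
    fread(path)
  }
  miss <- setdiff(unname(channel_map), names(d))
  if (length(miss) > 0L) {
    stop(sprintf("channels not found in '%s': %s; available channels: %s",
                 path, paste(miss, collapse = ", "),
                 paste(names(d), collapse = ", ")))
  }
  out <- data.table(FL1_A = as.numeric(d[[channel_map[["FL1_A"]]]]),
                    FL3_A = as.numeric(d[[channel_map[["FL3_A"]]]]))
  if ("well" %in% names(d)) out[, well := d$well]
  out[]
}

#' Read and write plate maps
#'
#' CSV schema: `plate_id`, `well`, `row_idx`, `col_idx`, `role`,
#' `compound_id`. Duplicate wells and unknown roles are rejected.
#'
#' @param layout A [plate_layout()].
#' @param path CSV path.
#'
#' @return `read_plate_map()` returns a validated `plate_layout`.
#' @export
write_plate_map <- function(layout, path) {
  fwrite(as.data.table(layout), path)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  d <- fread(path)
  .check_cols(d, c("well", "row_idx", "col_idx", "role"), "plate map", path)
  validate_plate_layout(d)
  setattr(d, "class", c("plate_layout", class(d)))
  d[]
}

#' Read and write multi-page TIFF image stacks
#'
#' Stacks are written as 16-bit multi-page TIFF; intensities are stored as
#' `value / 65535` and restored on read, so a round trip preserves integer
#' intensity values exactly.
#'
#' @param stack An [image_stack()].
#' @param path TIFF path.
#' @param pixel_size_um,frame_interval Acquisition metadata to attach on
#'   read (TIFF pages do not carry them).
#'
#' @return `read_image_stack()` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(stack$frames, function(f) pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, pixel_size_um = 0.65,
                             frame_interval = 1 / 48) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]
    round(f * 65535)
  })
  image_stack(frames, pixel_size_um, frame_interval)
}

#' Default run configuration
#'
#' All pipeline thresholds in one structured block, with defaults equal to
#' the assay's stated values: WHO class thresholds 25/80/5/11 (um/s, %),
#' the 85% motility hit cut (15% reduction), the 15% AR induction cut and
#' the 200-event floor.
#'
#' @return A nested list of parameter blocks.
#' @export
default_run_config <- function() {
  list(
    detect = list(feature_diameter = 9L, mass_threshold = 20000,
                  min_separation = 9),
    link = list(max_displacement_um = 12, min_track_length = 12L, memory = 0L),
    kinematics = list(window = 5L, min_points = 12L,
                      pm_vap_min = 25, pm_str_min = 80,
                      npm_vap_min = 5, npm_vsl_min = 11),
    plate = list(hit_cutoff_pct = 85, upregulator_cutoff_pct = 115,
                 zprime_warn = 0.4),
    ar = list(induction_threshold_pct = 15, min_events = 200L,
              min_pi_pos_frac = 0.02),
    dose_response = list(top_conc = 10, n = 8L, factor = 3),
    channels = list(FL1_A = "FL1_A", FL3_A = "FL3_A"),
    imaging = list(pixel_size_um = 0.65, frame_interval = 1 / 48),
    sim = list()
  )
}

#' Read a run configuration file
#'
#' A YAML file whose entries override [default_run_config()] blockwise.
#'
#' @param path YAML path, or `NULL` for the defaults.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

#' Write per-well result tables
#'
#' @param result A `plate_motility_result` or `plate_ar_result` (their
#'   `results` table is written) or any data.frame.
#' @param path CSV path.
#' @export
write_results <- function(result, path) {
  tab <- if (is.list(result) && !is.data.frame(result) &&
             !is.null(result$results)) result$results else result
  fwrite(as.data.table(tab), path)
  invisible(path)
}
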