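## Plate-level screening analytics: percent-of-control normalisation of the
## well median VCL, Z'-factor QC, hit calling and exclusions.

#' Percent-of-control normalisation
#'
#' `100 * well median VCL / reference`, where the reference is the median of
#' the plate's DMSO-well medians (robust to a single bad control well).
#'
#' @param well_median_vcl Numeric vector of well medians (um/s).
#' @param dmso_median_vcls Medians of the plate's DMSO wells (um/s).
#'
#' @return Percent-of-control values.
#' @export
percent_of_control <- function(well_median_vcl, dmso_median_vcls) {
  dmso_median_vcls <- dmso_median_vcls[!is.na(dmso_median_vcls)]
  if (length(dmso_median_vcls) < 1L) {
    stop("plate fails normalization: no DMSO reference wells")
  }
  ref <- median(dmso_median_vcls)
  if (!is.finite(ref) || ref <= 0) {
    stop("plate fails normalization: DMSO reference is zero or undefined")
  }
  100 * well_median_vcl / ref
}

#' Z'-factor assay-quality statistic
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample means
#' and sample standard deviations. May be negative; equals 1 in the
#' zero-variance limit. When the control means coincide the statistic is
#' undefined and `NA` is returned as a failed-QC sentinel.
#'
#' @param negative_values,positive_values Control readouts (>= 2 each).
#'
#' @return The Z'-factor (dimensionless), or `NA` if undefined.
#' @export
zprime <- function(negative_values, positive_values) {
  if (length(negative_values) < 2L || length(positive_values) < 2L) {
    stop("need at least 2 values per control group")
  }
  delta <- abs(mean(positive_values) - mean(negative_values))
  if (delta == 0) return(NA_real_)
  1 - 3 * (sd(positive_values) + sd(negative_values)) / delta
}

#' Flag wells for exclusion
#'
#' Flagged wells (autofocus errors, sticky compounds, low counts, ...) are
#' removed from normalisation and hit calling; the reasons are kept.
#'
#' @param well_results Per-well table with a `well` column.
#' @param flags `data.frame(well, flag)`; may list a well more than once.
#'
#' @return `well_results` with logical `excluded` and character `reason`
#'   columns added.
#' @export
exclude_wells <- function(well_results, flags = NULL) {
  res <- as.data.table(well_results)
  res[, excluded := FALSE]
  res[, reason := NA_character_]
  if (!is.null(flags) && nrow(flags) > 0L) {
    flags <- as.data.table(flags)
    why <- flags[, .(reason = paste(unique(flag), collapse = ";")), by = well]
    res[why, `:=`(excluded = TRUE, reason = i.reason), on = "well"]
  }
  res[]
}

#' Call motility hits from percent-of-control values
#'
#' A compound well is an inhibitor hit when its percent-of-control VCL falls
#' strictly below `hit_cutoff_pct` (the 15%-reduction rule), and is flagged
#' as a motility upregulator strictly above `upregulator_cutoff_pct`
#' (symmetric convention). Control and excluded wells are never called.
#'
#' @param plate_result Table with `well`, `role`, `pct_control` and
#'   optionally `excluded`.
#' @param hit_cutoff_pct Inhibitor cut-off (default 85).
#' @param upregulator_cutoff_pct Upregulator cut-off (default 115).
#'
#' @return The table with a `call` column
#'   (`inhibitor_hit|upregulator_flag|none`, `NA` for controls/excluded).
#' @export
call_motility_hits <- function(plate_result, hit_cutoff_pct = 85,
                               upregulator_cutoff_pct = 115) {
  res <- as.data.table(plate_result)
  if (!"excluded" %in% names(res)) res[, excluded := FALSE]
  res[, call := NA_character_]
  callable <- res$role == "compound" & !res$excluded & !is.na(res$pct_control)
  res[callable, call := fifelse(pct_control < hit_cutoff_pct, "inhibitor_hit",
                                fifelse(pct_control > upregulator_cutoff_pct,
                                        "upregulator_flag", "none"))]
  res[]
}

#' Full motility analysis of one plate
#'
#' Joins per-well motility summaries to the plate layout, applies
#' exclusions, normalises to the DMSO reference, computes the plate
#' Z'-factor on the percent-of-control values of the DMSO versus
#' pristimerin controls, and calls hits. Plates with Z' below
#' `zprime_warn` are flagged (not rejected).
#'
#' @param well_results Output of [well_motility_table()].
#' @param layout A [plate_layout()].
#' @param flags Optional `data.frame(well, flag)` of exclusions.
#' @param hit_cutoff_pct,upregulator_cutoff_pct Hit cut-offs.
#' @param zprime_warn Z' level below which the plate is flagged.
#'
#' @return A list of class `plate_motility_result`: `results` (per-well
#'   table with `pct_control` and `call`), `zprime`, `dmso_reference`,
#'   `excluded` (wells + reasons), `qc_flags`.
#' @export
analyze_plate_motility <- function(well_results, layout, flags = NULL,
                                   hit_cutoff_pct = 85,
                                   upregulator_cutoff_pct = 115,
                                   zprime_warn = 0.4) {
  validate_plate_layout(layout)
  res <- as.data.table(well_results)
  lay <- as.data.table(layout)[, .(well, row_idx, col_idx, role, compound_id)]
  res <- lay[res, on = "well"]
  ## wells flagged upstream (e.g. low_count) are excluded alongside input flags
  auto <- res[flags != "" & !is.na(flags), .(well, flag = flags)]
  flags <- rbind(as.data.table(flags), auto, fill = TRUE)
  res <- exclude_wells(res, flags)
  dmso <- res[role == "dmso" & !excluded, median_vcl]
  res[, pct_control := fifelse(excluded, NA_real_,
                               percent_of_control(median_vcl, dmso))]
  neg <- res[role == "dmso" & !excluded, pct_control]
  pos <- res[role == "pristimerin" & !excluded, pct_control]
  zp <- if (length(neg) >= 2L && length(pos) >= 2L) zprime(neg, pos) else NA_real_
  res <- call_motility_hits(res, hit_cutoff_pct, upregulator_cutoff_pct)
  qc <- character()
  if (is.na(zp)) qc <- c(qc, "zprime_undefined")
  else if (zp < zprime_warn) qc <- c(qc, "low_zprime")
  out <- list(results = res[],
              zprime = zp,
              dmso_reference = median(dmso),
              excluded = res[excluded == TRUE, .(well, reason)],
              qc_flags = qc)
  class(out) <- "plate_motility_result"
  out
}

#' @export
print.plate_motility_result <- function(x, ...) {
  hits <- x$results[call == "inhibitor_hit", .N]
  up <- x$results[call == "upregulator_flag", .N]
  cat(sprintf(paste0("<plate_motility_result: %d wells, Z' = %.3f, ",
                     "%d inhibitor hits, %d upregulator flags, %d excluded>\n"),
              nrow(x$results), x$zprime, hits, up, nrow(x$excluded)))
  invisible(x)
}

#' Export a plate metric as a heatmap grid
#'
#' Arranges a per-well metric on the plate grid for edge-effect inspection,
#' appending row and column means, and optionally writes a CSV and a PNG.
#'
#' @param plate_result A [analyze_plate_motility()] result or a per-well
#'   table with `row_idx`, `col_idx` and the metric column.
#' @param metric One of `"pct_control"`, `"median_vcl"`, `"n_tracks"`.
#' @param csv_path,png_path Optional output paths.
#'
#' @return Invisibly, a list with `grid` (rows x columns matrix),
#'   `row_means`, `col_means`.
#' @export
plate_heatmap <- function(plate_result,
                          metric = c("pct_control", "median_vcl", "n_tracks"),
                          csv_path = NULL, png_path = NULL) {
  metric <- match.arg(metric)
  res <- if (inherits(plate_result, "plate_motility_result")) {
    plate_result$results
  } else {
    as.data.table(plate_result)
  }
  stopifnot(all(c("row_idx", "col_idx", metric) %in% names(res)))
  nr <- max(res$row_idx)
  nc <- max(res$col_idx)
  grid <- matrix(NA_real_, nr, nc,
                 dimnames = list(LETTERS[seq_len(nr)], seq_len(nc)))
  grid[cbind(res$row_idx, res$col_idx)] <- res[[metric]]
  row_means <- rowMeans(grid, na.rm = TRUE)
  col_means <- colMeans(grid, na.rm = TRUE)
  if (!is.null(csv_path)) {
    out <- cbind(as.data.table(grid, keep.rownames = "row"),
                 row_mean = row_means)
    out <- rbind(out, c(list(row = "col_mean"), as.list(c(col_means, NA))),
                 use.names = FALSE)
    data.table::fwrite(out, csv_path)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 900, height = 640)
    graphics::par(mar = c(4, 4, 3, 2))
    graphics::image(x = seq_len(nc), y = seq_len(nr),
                    z = t(grid[nr:1, , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "column", ylab = "row", main = metric, yaxt = "n")
    graphics::axis(2, at = seq_len(nr), labels = rev(rownames(grid)))
    grDevices::dev.off()
  }
  invisible(list(grid = grid, row_means = row_means, col_means = col_means))
}
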