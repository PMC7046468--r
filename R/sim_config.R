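## Configuration objects for the synthetic-data generator.

#' Quadrant population codes
#'
#' Canonical order of the four propidium-iodide (Pi) / PNA-lectin populations
#' used throughout the flow-cytometry side of the package: live non-reacted
#' (Pi-PNA-), dead (Pi+PNA-), dead reacted (Pi+PNA+), live acrosome-reacted
#' (Pi-PNA+).
#'
#' @return Character vector of the four population codes.
#' @export
quadrant_populations <- function() {
  c("pi_neg_pna_neg", "pi_pos_pna_neg", "pi_pos_pna_pos", "pi_neg_pna_pos")
}

#' Configuration for simulated swimming tracks and rendered image stacks
#'
#' Defaults follow the acquisition geometry of the screening assay this
#' package models: 24 frames over 0.5 s (48 fps) of brightfield time-lapse
#' at 20x, with sperm heads appearing as compact bright spots after
#' contrast processing. The three kinematic classes are progressively
#' motile (PM: straight drift plus a sinusoidal flagellar-beat wobble),
#' non-progressively motile (NPM: correlated jitter around a slowly
#' drifting centre) and immotile (IM: isotropic Gaussian jitter).
#'
#' @param n_frames Number of frames per time-lapse series (>= 2).
#' @param frame_interval Seconds between frames (default 1/48 s).
#' @param pixel_size_um Microns per pixel.
#' @param field_size_um Field edge lengths in microns, length-2 (x, y).
#' @param n_cells_per_class Named counts `c(pm=, npm=, im=)` per field.
#' @param pm_speed_mean,pm_speed_sd Mean and SD of PM drift speed (um/s).
#' @param pm_beat_amplitude_um Lateral beat amplitude (um).
#' @param pm_beat_frequency_hz Beat frequency (Hz).
#' @param npm_jitter_scale_um Stationary SD of the NPM positional jitter (um).
#' @param npm_jitter_corr Frame-to-frame correlation of the NPM jitter.
#' @param npm_drift_speed Speed of the slowly drifting NPM centre (um/s).
#' @param im_jitter_scale_um SD of the IM isotropic jitter (um).
#' @param psf_sigma_px Gaussian spot sigma used when rendering (pixels).
#' @param head_intensity Peak spot amplitude above background (intensity units).
#' @param background_level Mean background intensity.
#' @param noise_sd SD of the additive Gaussian pixel noise.
#' @param invert Render dark heads on a bright background instead.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#'
#' @return A list of class `motility_sim_config`.
#' @export
motility_sim_config <- function(n_frames = 24L,
                                frame_interval = 1 / 48,
                                pixel_size_um = 0.65,
                                field_size_um = c(1024, 1024) * 0.65,
                                n_cells_per_class = c(pm = 120L, npm = 50L, im = 30L),
                                pm_speed_mean = 100,
                                pm_speed_sd = 20,
                                pm_beat_amplitude_um = 2,
                                pm_beat_frequency_hz = 14,
                                npm_jitter_scale_um = 0.8,
                                npm_jitter_corr = 0.7,
                                npm_drift_speed = 5,
                                im_jitter_scale_um = 0.1,
                                psf_sigma_px = 1.5,
                                head_intensity = 8000,
                                background_level = 1000,
                                noise_sd = 50,
                                invert = FALSE,
                                seed = NULL) {
  if (length(field_size_um) == 1L) field_size_um <- rep(field_size_um, 2L)
  cfg <- list(
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    pixel_size_um = pixel_size_um, field_size_um = field_size_um,
    n_cells_per_class = .as_class_counts(n_cells_per_class),
    pm_speed_mean = pm_speed_mean, pm_speed_sd = pm_speed_sd,
    pm_beat_amplitude_um = pm_beat_amplitude_um,
    pm_beat_frequency_hz = pm_beat_frequency_hz,
    npm_jitter_scale_um = npm_jitter_scale_um,
    npm_jitter_corr = npm_jitter_corr,
    npm_drift_speed = npm_drift_speed,
    im_jitter_scale_um = im_jitter_scale_um,
    psf_sigma_px = psf_sigma_px, head_intensity = head_intensity,
    background_level = background_level, noise_sd = noise_sd,
    invert = isTRUE(invert), seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "motility_sim_config"
  validate_motility_sim_config(cfg)
  cfg
}

.as_class_counts <- function(x) {
  if (is.null(names(x))) names(x) <- c("pm", "npm", "im")
  stopifnot(all(c("pm", "npm", "im") %in% names(x)))
  counts <- as.integer(x[c("pm", "npm", "im")])
  names(counts) <- c("pm", "npm", "im")
  counts
}

#' @rdname motility_sim_config
#' @param config Object to validate.
#' @export
validate_motility_sim_config <- function(config) {
  stopifnot(inherits(config, "motility_sim_config"))
  with(config, {
    if (n_frames < 2L) stop("n_frames must be >= 2")
    if (frame_interval <= 0) stop("frame_interval must be > 0")
    if (any(field_size_um <= 0) || pixel_size_um <= 0) {
      stop("field and pixel sizes must be > 0")
    }
    if (any(n_cells_per_class < 0L)) stop("cell counts must be >= 0")
    stopifnot(
      pm_speed_mean >= 0, pm_speed_sd >= 0, pm_beat_amplitude_um >= 0,
      pm_beat_frequency_hz >= 0, npm_jitter_scale_um >= 0,
      npm_jitter_corr >= 0, npm_jitter_corr < 1,
      im_jitter_scale_um >= 0, psf_sigma_px > 0, noise_sd >= 0
    )
  })
  invisible(config)
}

#' Configuration for simulated flow-cytometry event clouds
#'
#' Events are drawn from a four-component mixture of bivariate Gaussians on
#' (log10 FL1, log10 FL3) and exported on the linear fluorescence scale.
#' The four components are the Pi/PNA quadrant populations in the order of
#' [quadrant_populations()]. Default centres put the stained/unstained
#' populations roughly two decades apart, as on a typical screening
#' cytometer, and default proportions describe a healthy vehicle-control
#' well: mostly live non-reacted cells, a dead fraction, and ~5% live
#' acrosome-reacted background.
#'
#' @param n_events Number of events to draw (>= 0).
#' @param proportions Named fractions per population, summing to 1.
#' @param centres 4x2 matrix of per-population (log10 FL1, log10 FL3) means.
#' @param spreads 4x2 matrix of per-population log10 SDs (or a scalar).
#' @param seed Optional integer seed.
#'
#' @return A list of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events = 4000L,
                            proportions = c(pi_neg_pna_neg = 0.70,
                                            pi_pos_pna_neg = 0.18,
                                            pi_pos_pna_pos = 0.07,
                                            pi_neg_pna_pos = 0.05),
                            centres = NULL,
                            spreads = 0.25,
                            seed = NULL) {
  pops <- quadrant_populations()
  if (is.null(centres)) {
    centres <- rbind(c(2, 2), c(2, 4), c(4, 4), c(4, 2))
  }
  centres <- matrix(as.numeric(centres), nrow = 4L, ncol = 2L,
                    dimnames = list(pops, c("log10_fl1", "log10_fl3")))
  if (length(spreads) == 1L) spreads <- matrix(spreads, 4L, 2L)
  spreads <- matrix(as.numeric(spreads), nrow = 4L, ncol = 2L,
                    dimnames = dimnames(centres))
  if (is.null(names(proportions))) names(proportions) <- pops
  proportions <- proportions[pops]
  cfg <- list(
    n_events = as.integer(n_events), proportions = proportions,
    centres = centres, spreads = spreads,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "flow_sim_config"
  validate_flow_sim_config(cfg)
  cfg
}

#' @rdname flow_sim_config
#' @param config Object to validate.
#' @export
validate_flow_sim_config <- function(config) {
  stopifnot(inherits(config, "flow_sim_config"))
  if (config$n_events < 0L) stop("n_events must be >= 0")
  p <- config$proportions
  if (anyNA(p) || any(p < 0)) stop("proportions must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  if (any(config$spreads <= 0)) stop("spreads must be > 0")
  invisible(config)
}

#' Configuration for a whole simulated screening plate
#'
#' Wraps a plate layout, per-well compound effects and the base track and
#' flow-event generators into one reproducible object. A well's
#' `motility_scale` multiplies every kinematic magnitude of its cells (PM
#' drift speed and beat amplitude, NPM/IM jitter and drift), so the well's
#' median curvilinear velocity scales proportionally; `ar_induction` is an
#' added live acrosome-reacted (Pi-PNA+) fraction taken from the live
#' non-reacted pool. Vehicle (DMSO) wells always use scale 1 and induction 0.
#' Pristimerin positive-control wells draw their per-well efficacy from a
#' truncated normal (donor-pool variability of the positive control);
#' A23187 wells use the configured AR induction. A multiplicative per-well
#' biological factor (`well_effect_sd`) models well-to-well variability.
#'
#' @param layout A plate layout, see [plate_layout()].
#' @param effects Optional `data.frame(well, motility_scale, ar_induction)`
#'   for compound wells; wells without an entry default to no effect.
#' @param motility_config Base [motility_sim_config()] (per imaging position).
#' @param flow_config Base [flow_sim_config()].
#' @param pristimerin_scale_mean,pristimerin_scale_sd Mean/SD of the
#'   positive-control motility scale (truncated to [0.02, 0.8]).
#' @param a23187_ar_induction Added live-reacted fraction in A23187 wells.
#' @param well_effect_sd SD of the multiplicative per-well biological factor.
#' @param n_positions Imaging positions per well (the assay uses 2).
#' @param seed Integer root seed; per-well streams are derived from it.
#'
#' @return A list of class `plate_sim_config`.
#' @export
plate_sim_config <- function(layout = plate_layout(),
                             effects = NULL,
                             motility_config = motility_sim_config(),
                             flow_config = flow_sim_config(),
                             pristimerin_scale_mean = 0.2,
                             pristimerin_scale_sd = 0.09,
                             a23187_ar_induction = 0.10,
                             well_effect_sd = 0.025,
                             n_positions = 2L,
                             seed = 1L) {
  cfg <- list(
    layout = layout, effects = effects,
    motility_config = motility_config, flow_config = flow_config,
    pristimerin_scale_mean = pristimerin_scale_mean,
    pristimerin_scale_sd = pristimerin_scale_sd,
    a23187_ar_induction = a23187_ar_induction,
    well_effect_sd = well_effect_sd,
    n_positions = as.integer(n_positions),
    seed = as.integer(seed)
  )
  class(cfg) <- "plate_sim_config"
  validate_plate_sim_config(cfg)
  cfg
}

#' @rdname plate_sim_config
#' @param config Object to validate.
#' @export
validate_plate_sim_config <- function(config) {
  stopifnot(inherits(config, "plate_sim_config"))
  validate_plate_layout(config$layout)
  validate_motility_sim_config(config$motility_config)
  validate_flow_sim_config(config$flow_config)
  roles <- config$layout$role
  if (!any(roles == "dmso")) stop("layout must contain at least one DMSO well")
  if (!any(roles == "pristimerin") || !any(roles == "a23187")) {
    stop("layout must contain at least one positive-control well per assay")
  }
  eff <- config$effects
  if (!is.null(eff)) {
    stopifnot(all(c("well", "motility_scale", "ar_induction") %in% names(eff)))
    if (!all(eff$well %in% config$layout$well)) {
      stop("effects reference wells absent from the layout")
    }
    if (any(eff$motility_scale < 0 | eff$motility_scale > 1.5)) {
      stop("motility_scale must lie in [0, 1.5]")
    }
    if (any(eff$ar_induction < 0 | eff$ar_induction > 1)) {
      stop("ar_induction must lie in [0, 1]")
    }
  }
  stopifnot(config$well_effect_sd >= 0, config$n_positions >= 1L,
            config$a23187_ar_induction >= 0, config$a23187_ar_induction <= 1)
  invisible(config)
}

## Rescale every kinematic magnitude of a motility config by k (well effect).
scale_motility_config <- function(config, k) {
  config$pm_speed_mean <- config$pm_speed_mean * k
  config$pm_speed_sd <- config$pm_speed_sd * k
  config$pm_beat_amplitude_um <- config$pm_beat_amplitude_um * k
  config$npm_jitter_scale_um <- config$npm_jitter_scale_um * k
  config$npm_drift_speed <- config$npm_drift_speed * k
  config$im_jitter_scale_um <- config$im_jitter_scale_um * k
  config
}
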