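## Rendering of simulated tracks into noisy time-lapse image stacks.

#' Construct an image stack
#'
#' @param frames List of numeric matrices (rows = y, columns = x), all the
#'   same shape.
#' @param pixel_size_um Microns per pixel.
#' @param frame_interval Seconds between frames.
#'
#' @return A list of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            pixel_size_um > 0, frame_interval > 0)
  dims <- vapply(frames, dim, integer(2L))
  if (length(frames) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    stop("all frames must have the same shape")
  }
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack: %d frames of %d x %d px, %.3g um/px, %.4g s/frame>\n",
              length(x$frames), d[1], d[2], x$pixel_size_um, x$frame_interval))
  invisible(x)
}

## Pixel convention: pixel (row i, col j), 1-based, has its centre at
## x_um = (j - 0.5) * pixel_size, y_um = (i - 0.5) * pixel_size; the image
## origin is the top-left corner, x runs rightward, y downward.
.um_to_px <- function(u, pixel_size) u / pixel_size + 0.5
.px_to_um <- function(p, pixel_size) (p - 0.5) * pixel_size

#' Render simulated tracks into a noisy image stack
#'
#' Each head is drawn as a 2-D Gaussian spot of sigma `psf_sigma_px` centred
#' at its track position, on a constant background with additive Gaussian
#' noise. By default heads are bright on a dark background (the convention
#' assumed by the mass-based detector); `invert = TRUE` renders dark heads.
#'
#' @param tracks Long track table (`track_id`, `frame`, `x_um`, `y_um`).
#' @param config A [motility_sim_config()].
#' @param seed Optional integer seed for the pixel noise.
#'
#' @return An [image_stack()] with `config$n_frames` frames.
#' @export
render_stack <- function(tracks, config = motility_sim_config(),
                         seed = config$seed) {
  validate_motility_sim_config(config)
  tracks <- as.data.table(tracks)
  fx <- config$field_size_um[1]
  fy <- config$field_size_um[2]
  if (nrow(tracks) > 0L &&
      (min(tracks$x_um) < 0 || max(tracks$x_um) > fx ||
       min(tracks$y_um) < 0 || max(tracks$y_um) > fy)) {
    stop("track points fall outside the field")
  }
  if (!is.null(seed)) set.seed(seed)
  px <- config$pixel_size_um
  w <- max(1L, round(fx / px))
  h <- max(1L, round(fy / px))
  sig <- config$psf_sigma_px
  halo <- ceiling(4 * sig)
  amp <- if (config$invert) -config$head_intensity else config$head_intensity
  frames <- vector("list", config$n_frames)
  for (f in seq_len(config$n_frames) - 1L) {
    img <- matrix(config$background_level, nrow = h, ncol = w)
    pts <- tracks[frame == f]
    if (nrow(pts) > 0L) {
      cx <- .um_to_px(pts$x_um, px)
      cy <- .um_to_px(pts$y_um, px)
      for (i in seq_len(nrow(pts))) {
        jr <- max(1L, floor(cx[i] - halo)):min(w, ceiling(cx[i] + halo))
        ir <- max(1L, floor(cy[i] - halo)):min(h, ceiling(cy[i] + halo))
        gx <- exp(-((jr - cx[i])^2) / (2 * sig^2))
        gy <- exp(-((ir - cy[i])^2) / (2 * sig^2))
        img[ir, jr] <- img[ir, jr] + amp * (gy %o% gx)
      }
    }
    if (config$noise_sd > 0) {
      img <- img + matrix(rnorm(h * w, 0, config$noise_sd), h, w)
    }
    frames[[f + 1L]] <- pmax(img, 0)
  }
  image_stack(frames, px, config$frame_interval)
}
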