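## Crocker-Grier-style sperm-head detection: difference-of-Gaussians
## band-pass, strict local maxima with minimum-separation suppression, and
## one pass of intensity-weighted centroid refinement.

#' Detection parameters
#'
#' @param feature_diameter Odd spot diameter in pixels (>= 3). The band-pass
#'   uses Gaussian scales `feature_diameter/7` (small) and `feature_diameter`
#'   (large); the centroid window has radius `floor(feature_diameter/2)`.
#' @param mass_threshold Minimum integrated band-passed intensity of a
#'   detection. The default suits stacks rendered with the default
#'   [motility_sim_config()] intensity scale.
#' @param min_separation Minimum distance between detections in pixels.
#'
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(feature_diameter = 9L, mass_threshold = 20000,
                          min_separation = 9) {
  feature_diameter <- as.integer(feature_diameter)
  if (feature_diameter < 3L || feature_diameter %% 2L == 0L) {
    stop("feature_diameter must be odd and >= 3")
  }
  stopifnot(min_separation > 0)
  structure(list(feature_diameter = feature_diameter,
                 mass_threshold = mass_threshold,
                 min_separation = min_separation),
            class = "detect_params")
}

## Separable Gaussian blur with edge replication. A direct spatial
## convolution (stats::filter) beats FFT-based filtering at these kernel
## sizes and keeps the detector dependency-free.
.gaussian_blur <- function(m, sigma) {
  k <- ceiling(3 * sigma)
  ker <- exp(-((-k:k)^2) / (2 * sigma^2))
  ker <- ker / sum(ker)
  pad <- function(mm) {
    rbind(mm[rep(1L, k), , drop = FALSE], mm,
          mm[rep(nrow(mm), k), , drop = FALSE])
  }
  blur_cols <- function(mm) {
    out <- stats::filter(pad(mm), ker, sides = 2L)
    out[(k + 1L):(k + nrow(mm)), , drop = FALSE]
  }
  t(blur_cols(t(blur_cols(m))))
}

## Difference-of-Gaussians band-pass, clipped at zero.
.bandpass <- function(frame, feature_diameter) {
  bp <- .gaussian_blur(frame, feature_diameter / 7) -
    .gaussian_blur(frame, feature_diameter)
  pmax(bp, 0)
}

## Strict 3x3 local maxima of a matrix, excluding a margin, as (row, col).
.local_maxima <- function(m, margin) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L * margin + 1L || nc < 2L * margin + 1L) {
    return(cbind(row = integer(), col = integer()))
  }
  ri <- (margin + 1L):(nr - margin)
  ci <- (margin + 1L):(nc - margin)
  core <- m[ri, ci, drop = FALSE]
  ok <- core > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ok <- ok & (core > m[ri + dr, ci + dc, drop = FALSE])
  }
  idx <- which(ok, arr.ind = TRUE)
  cbind(row = idx[, 1L] + margin, col = idx[, 2L] + margin)
}

#' Detect sperm heads in one frame
#'
#' Applies a difference-of-Gaussians band-pass, finds strict local maxima
#' separated by at least `min_separation` pixels (brighter peaks win), and
#' refines each candidate to the intensity-weighted centroid of its feature
#' window on the band-passed image. Candidates whose integrated intensity
#' (mass) falls below `mass_threshold` are discarded.
#'
#' @param frame Numeric matrix (rows = y, columns = x), all values finite.
#' @param params A [detect_params()].
#' @param pixel_size_um Microns per pixel used to report positions.
#'
#' @return A `data.table` with columns `x_um`, `y_um`, `mass`.
#' @export
detect_heads <- function(frame, params = detect_params(), pixel_size_um = 1) {
  if (inherits(frame, "image_stack")) {
    stop("pass a single frame matrix; use detect_stack() for stacks")
  }
  frame <- as.matrix(frame)
  if (!all(is.finite(frame))) stop("frame contains non-finite pixels")
  stopifnot(pixel_size_um > 0)
  fd <- params$feature_diameter
  rw <- fd %/% 2L
  bp <- .bandpass(frame, fd)
  peaks <- .local_maxima(bp, margin = rw)
  ## discard noise peaks that cannot reach the mass threshold: the window
  ## mass of a candidate is at most (feature window area) x (window maximum)
  if (nrow(peaks) > 0L && params$mass_threshold > 0) {
    floor_val <- params$mass_threshold / fd^2
    peaks <- peaks[bp[peaks] >= floor_val, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) {
    return(data.table(x_um = numeric(), y_um = numeric(), mass = numeric()))
  }
  ## minimum-separation suppression: strongest peak wins
  vals <- bp[peaks]
  ord <- order(vals, decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  keep <- logical(nrow(peaks))
  kept <- matrix(numeric(0), 0L, 2L)
  min_sep2 <- params$min_separation^2
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (nrow(kept) == 0L ||
        all((kept[, 1L] - p[1L])^2 + (kept[, 2L] - p[2L])^2 >= min_sep2)) {
      keep[i] <- TRUE
      kept <- rbind(kept, p)
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  ## one iteration of intensity-weighted centroid refinement
  nr <- nrow(bp); nc <- ncol(bp)
  n <- nrow(peaks)
  cx <- numeric(n); cy <- numeric(n); mass <- numeric(n)
  for (i in seq_len(n)) {
    r0 <- max(1L, peaks[i, 1L] - rw); r1 <- min(nr, peaks[i, 1L] + rw)
    c0 <- max(1L, peaks[i, 2L] - rw); c1 <- min(nc, peaks[i, 2L] + rw)
    w <- bp[r0:r1, c0:c1, drop = FALSE]
    m <- sum(w)
    if (m <= 0) next
    cy[i] <- sum(rowSums(w) * (r0:r1)) / m
    cx[i] <- sum(colSums(w) * (c0:c1)) / m
    mass[i] <- m
  }
  ok <- mass >= params$mass_threshold
  data.table(x_um = .px_to_um(cx[ok], pixel_size_um),
             y_um = .px_to_um(cy[ok], pixel_size_um),
             mass = mass[ok])
}

#' Detect sperm heads in every frame of a stack
#'
#' @param stack An [image_stack()].
#' @param params A [detect_params()].
#'
#' @return A `data.table` with `frame` (0-based), `x_um`, `y_um`, `mass`.
#' @export
detect_stack <- function(stack, params = detect_params()) {
  stopifnot(inherits(stack, "image_stack"))
  out <- lapply(seq_along(stack$frames), function(f) {
    d <- detect_heads(stack$frames[[f]], params, stack$pixel_size_um)
    if (nrow(d) > 0L) d[, frame := f - 1L]
    d
  })
  out <- rbindlist(out, fill = TRUE)
  if (nrow(out) == 0L) {
    return(data.table(frame = integer(), x_um = numeric(),
                      y_um = numeric(), mass = numeric()))
  }
  setcolorder(out, c("frame", "x_um", "y_um", "mass"))
  out[]
}
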