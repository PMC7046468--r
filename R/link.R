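## Frame-to-frame linking of detections into tracks.
##
## Between consecutive frames, detections are assigned to existing track
## heads so as to minimise the total squared displacement, subject to every
## link being shorter than max_displacement. Candidate links are split into
## connected subnetworks; small subnetworks (<= 7 heads and <= 7 detections,
## as in the classic Crocker-Grier formulation) are solved exactly by
## enumeration with a null-link penalty of max_displacement^2 per unmatched
## head or detection, larger ones greedily by ascending distance. Unmatched
## detections start new tracks; tracks not extended for more than `memory`
## frames are terminated.

#' Linking parameters
#'
#' @param max_displacement_um Maximum link length per frame, in microns. The
#'   default 12 um/frame (~576 um/s at 48 fps) sits above any plausible
#'   curvilinear velocity, while staying conservative enough to avoid
#'   cross-track links.
#' @param min_track_length Minimum number of points for a track to be kept.
#' @param memory Frames a track may go undetected before termination.
#'
#' @return A list of class `link_params`.
#' @export
link_params <- function(max_displacement_um = 12, min_track_length = 12L,
                        memory = 0L) {
  stopifnot(max_displacement_um > 0, min_track_length >= 2L, memory >= 0L)
  structure(list(max_displacement_um = max_displacement_um,
                 min_track_length = as.integer(min_track_length),
                 memory = as.integer(memory)),
            class = "link_params")
}

## Connected components of a bipartite candidate graph given as an
## index-pair matrix (head i, detection j). Returns a list of components,
## each with $heads and $dets index vectors.
.bipartite_components <- function(pairs, n_heads, n_dets) {
  head_adj <- split(pairs[, 2L], pairs[, 1L])
  det_adj <- split(pairs[, 1L], pairs[, 2L])
  seen_h <- logical(n_heads)
  seen_d <- logical(n_dets)
  comps <- list()
  for (h0 in unique(pairs[, 1L])) {
    if (seen_h[h0]) next
    hs <- integer(0); ds <- integer(0)
    queue_h <- h0
    queue_d <- integer(0)
    seen_h[h0] <- TRUE
    while (length(queue_h) > 0L || length(queue_d) > 0L) {
      if (length(queue_h) > 0L) {
        h <- queue_h[1L]; queue_h <- queue_h[-1L]
        hs <- c(hs, h)
        for (d in head_adj[[as.character(h)]]) {
          if (!seen_d[d]) { seen_d[d] <- TRUE; queue_d <- c(queue_d, d) }
        }
      } else {
        d <- queue_d[1L]; queue_d <- queue_d[-1L]
        ds <- c(ds, d)
        for (h in det_adj[[as.character(d)]]) {
          if (!seen_h[h]) { seen_h[h] <- TRUE; queue_h <- c(queue_h, h) }
        }
      }
    }
    comps[[length(comps) + 1L]] <- list(heads = hs, dets = ds)
  }
  comps
}

## Exact minimal-cost assignment within one subnetwork by recursion over
## heads: each head links to one free candidate detection or to nothing.
## Cost = sum of squared link distances + null_cost per unmatched head and
## per unmatched detection. Returns an integer vector over heads (0 = null).
.assign_exact <- function(d2, cand, null_cost) {
  n_h <- nrow(d2)
  n_d <- ncol(d2)
  best <- list(cost = Inf, match = integer(n_h))
  used <- logical(n_d)
  cur <- integer(n_h)
  recurse <- function(h, acc) {
    if (acc >= best$cost) return(invisible())
    if (h > n_h) {
      cost <- acc + null_cost * sum(!used)
      if (cost < best$cost) best <<- list(cost = cost, match = cur)
      return(invisible())
    }
    for (d in cand[[h]]) {
      if (!used[d]) {
        used[d] <<- TRUE
        cur[h] <<- d
        recurse(h + 1L, acc + d2[h, d])
        used[d] <<- FALSE
      }
    }
    cur[h] <<- 0L
    recurse(h + 1L, acc + null_cost)
    invisible()
  }
  recurse(1L, 0)
  best$match
}

## Greedy fallback: accept candidate pairs by ascending distance.
.assign_greedy <- function(pairs, d2v, n_heads) {
  match <- integer(n_heads)
  used_d <- logical(max(pairs[, 2L]))
  for (k in order(d2v)) {
    h <- pairs[k, 1L]; d <- pairs[k, 2L]
    if (match[h] == 0L && !used_d[d]) {
      match[h] <- d
      used_d[d] <- TRUE
    }
  }
  match
}

#' Link per-frame detections into tracks
#'
#' @param detections A `data.table`/data.frame with columns `frame`
#'   (0-based, integers), `x_um`, `y_um`.
#' @param params A [link_params()].
#' @param frame_interval Seconds between frames, carried on the output.
#'
#' @return A `data.table` with `track_id`, `frame`, `x_um`, `y_um`, sorted
#'   by track and frame; only tracks with at least `min_track_length` points
#'   are kept. Attributes `n_detections` and `n_discarded_points` record the
#'   detection bookkeeping (every detection is used by exactly one raw
#'   track; discarded points are those on tracks shorter than the minimum).
#' @export
link_tracks <- function(detections, params = link_params(),
                        frame_interval = 1 / 48) {
  detections <- as.data.table(detections)
  empty <- data.table(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric())
  setattr(empty, "frame_interval", frame_interval)
  if (nrow(detections) == 0L) {
    setattr(empty, "n_detections", 0L)
    setattr(empty, "n_discarded_points", 0L)
    return(empty)
  }
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  maxd2 <- params$max_displacement_um^2

  frames <- sort(unique(detections$frame))
  by_frame <- split(detections[, .(x_um, y_um)], detections$frame)

  ## growing per-track point store
  tr_frames <- list(); tr_x <- list(); tr_y <- list()
  active_id <- integer(0)      # indices into tr_*
  active_x <- numeric(0); active_y <- numeric(0); active_last <- integer(0)
  n_tracks <- 0L

  start_tracks <- function(f, xs, ys) {
    for (i in seq_along(xs)) {
      n_tracks <<- n_tracks + 1L
      tr_frames[[n_tracks]] <<- f
      tr_x[[n_tracks]] <<- xs[i]
      tr_y[[n_tracks]] <<- ys[i]
      active_id <<- c(active_id, n_tracks)
      active_x <<- c(active_x, xs[i])
      active_y <<- c(active_y, ys[i])
      active_last <<- c(active_last, f)
    }
  }

  for (f in frames) {
    pts <- by_frame[[as.character(f)]]
    xs <- pts$x_um; ys <- pts$y_um
    n_d <- length(xs)
    ## retire tracks that exceeded the memory window
    alive <- active_last >= f - 1L - params$memory
    active_id <- active_id[alive]; active_x <- active_x[alive]
    active_y <- active_y[alive]; active_last <- active_last[alive]
    n_h <- length(active_id)
    if (n_h == 0L) {
      start_tracks(f, xs, ys)
      next
    }
    d2 <- outer(active_x, xs, "-")^2 + outer(active_y, ys, "-")^2
    cand_idx <- which(d2 <= maxd2, arr.ind = TRUE)
    if (nrow(cand_idx) == 0L) {
      start_tracks(f, xs, ys)
      next
    }
    match <- integer(n_h)
    comps <- .bipartite_components(cand_idx, n_h, n_d)
    for (cp in comps) {
      if (length(cp$heads) <= 7L && length(cp$dets) <= 7L) {
        sub_d2 <- d2[cp$heads, cp$dets, drop = FALSE]
        cand <- lapply(seq_along(cp$heads), function(i) {
          which(sub_d2[i, ] <= maxd2)
        })
        sub_match <- .assign_exact(sub_d2, cand, maxd2)
        hit <- sub_match > 0L
        match[cp$heads[hit]] <- cp$dets[sub_match[hit]]
      } else {
        in_comp <- cand_idx[, 1L] %in% cp$heads & cand_idx[, 2L] %in% cp$dets
        sub_pairs <- cand_idx[in_comp, , drop = FALSE]
        gm <- .assign_greedy(sub_pairs, d2[sub_pairs], n_h)
        match[cp$heads] <- gm[cp$heads]
      }
    }
    ## extend matched tracks
    for (h in which(match > 0L)) {
      id <- active_id[h]
      d <- match[h]
      tr_frames[[id]] <- c(tr_frames[[id]], f)
      tr_x[[id]] <- c(tr_x[[id]], xs[d])
      tr_y[[id]] <- c(tr_y[[id]], ys[d])
      active_x[h] <- xs[d]; active_y[h] <- ys[d]; active_last[h] <- f
    }
    ## unmatched detections start new tracks
    new_d <- setdiff(seq_len(n_d), match[match > 0L])
    start_tracks(f, xs[new_d], ys[new_d])
  }

  lens <- lengths(tr_frames)
  keep <- which(lens >= params$min_track_length)
  if (length(keep) == 0L) {
    setattr(empty, "n_detections", nrow(detections))
    setattr(empty, "n_discarded_points", nrow(detections))
    return(empty)
  }
  out <- data.table(
    track_id = rep(seq_along(keep), times = lens[keep]),
    frame = unlist(tr_frames[keep], use.names = FALSE),
    x_um = unlist(tr_x[keep], use.names = FALSE),
    y_um = unlist(tr_y[keep], use.names = FALSE)
  )
  setorder(out, track_id, frame)
  setattr(out, "frame_interval", frame_interval)
  setattr(out, "n_detections", nrow(detections))
  setattr(out, "n_discarded_points", nrow(detections) - nrow(out))
  out[]
}

#' Merge track sets from the two imaging positions of a well
#'
#' The assay images two positions per well, separated by a 400 um gap so no
#' sperm is counted twice; well-level analysis simply pools the two track
#' sets with re-assigned unique track ids.
#'
#' @param ... Two or more track tables (`track_id`, `frame`, `x_um`, `y_um`).
#'
#' @return One combined `data.table` with unique `track_id`s and a
#'   `position` column recording the source set.
#' @export
merge_positions <- function(...) {
  sets <- lapply(list(...), as.data.table)
  offset <- 0L
  out <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    s <- copy(sets[[k]])
    if (nrow(s) == 0L) next
    old <- sort(unique(s$track_id))
    s[, track_id := offset + match(track_id, old)]
    s[, position := k]
    offset <- offset + length(old)
    out[[k]] <- s
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    res <- data.table(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(), position = integer())
  }
  res[]
}
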