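# Nucleus detection, track linking, migration metrics, and durotactic turn
# angles.
#
# Tracks are stored in long format: a data.frame with columns
# cell (id), t (minutes), x, y (um).

#' Detect nuclei in a fluorescence frame
#'
#' Threshold (Otsu by default) + connected components + centroids. Intended
#' for well-separated stained nuclei; merged nuclei produce a single
#' centroid, which downstream area-outlier checks can flag.
#'
#' @param frame Single-channel image matrix.
#' @param min_area Minimum component area, px^2.
#' @param threshold `"otsu"` or a numeric intensity cutoff.
#'
#' @return data.frame with `x`, `y` (px, pixel-centred), `area` (px^2); zero
#'   rows for an empty frame.
#' @export
detect_nuclei <- function(frame, min_area = 20, threshold = "otsu") {
  stopifnot(is.matrix(frame))
  thr <- if (identical(threshold, "otsu")) otsu_threshold(frame) else threshold
  mask <- frame > thr
  if (!any(mask)) {
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0)))
  }
  labels <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(frame), ncol(frame)))
  labels <- as.matrix(labels)
  ids <- seq_len(max(labels))
  area <- tabulate(labels[labels > 0L], nbins = max(labels))
  keep <- which(area >= min_area)
  if (length(keep) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0)))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  cx <- tapply(idx[, 2], lab, mean)[as.character(keep)]
  cy <- tapply(idx[, 1], lab, mean)[as.character(keep)]
  data.frame(x = as.numeric(cx), y = as.numeric(cy), area = area[keep])
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking with one-frame gap
#' closing: candidate links are sorted by distance and accepted in ascending
#' order (each detection and each track used at most once), which resolves
#' crossing-cell ties by minimal total cost among the greedy choices. Links
#' longer than `max_step` (per elapsed frame) are forbidden; unlinked
#' detections start new tracks.
#'
#' @param detections List (one element per frame) of data.frames with `x`,
#'   `y` in um.
#' @param dt Frame interval, minutes.
#' @param max_step Maximum allowed displacement per frame interval, um.
#'
#' @return Tracks data.frame: `cell`, `t` (minutes), `x`, `y` (um).
#' @export
link_tracks <- function(detections, dt = 15, max_step = 20) {
  stopifnot(is.list(detections), length(detections) >= 2L)
  tracks <- list()           # per track: list(rows = data.frame, last_frame)
  active <- integer(0)
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    if (is.null(det) || nrow(det) == 0L) next
    n_det <- nrow(det)
    cand <- NULL
    if (length(active)) {
      for (a in seq_along(active)) {
        tr <- tracks[[active[a]]]
        gap <- f - tr$last_frame
        if (gap > 2L) next                       # at most one missed frame
        last <- tr$rows[nrow(tr$rows), ]
        d <- sqrt((det$x - last$x)^2 + (det$y - last$y)^2)
        ok <- which(d <= max_step * gap)
        if (length(ok)) {
          cand <- rbind(cand, data.frame(track = active[a], det = ok,
                                         dist = d[ok]))
        }
      }
    }
    used_det <- rep(FALSE, n_det)
    used_trk <- integer(0)
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$dist), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        tr <- cand$track[k]; dd <- cand$det[k]
        if (used_det[dd] || tr %in% used_trk) next
        tracks[[tr]]$rows <- rbind(tracks[[tr]]$rows,
                                   data.frame(frame = f, x = det$x[dd],
                                              y = det$y[dd]))
        tracks[[tr]]$last_frame <- f
        used_det[dd] <- TRUE
        used_trk <- c(used_trk, tr)
      }
    }
    for (dd in which(!used_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        rows = data.frame(frame = f, x = det$x[dd], y = det$y[dd]),
        last_frame = f)
    }
    active <- which(vapply(tracks, function(tr) tr$last_frame >= f - 1L, TRUE))
  }
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    r <- tracks[[i]]$rows
    data.frame(cell = i, t = (r$frame - 1) * dt, x = r$x, y = r$y)
  }))
  rownames(out) <- NULL
  out
}

#' Migration metrics for one track
#'
#' Maximum displacement is the largest Euclidean distance between the cell's
#' position at t = 0 and its position at any later frame; path length is the
#' summed step length; a cell is classified migrating when its maximum
#' displacement strictly exceeds the threshold (default 50 um). An
#' alternative classifier based on leaving a circle of twice the cell
#' diameter is available via `cell_diameter`.
#'
#' @param track data.frame with `t` (minutes), `x`, `y` (um), >= 2 rows.
#' @param threshold Migration threshold on maximum displacement, um.
#' @param cell_diameter If supplied, classify instead by displacement beyond
#'   `2 * cell_diameter` (um).
#'
#' @return List: `max_displacement` (um), `path_length` (um), `mean_speed`
#'   (um/h), `migrating`, `threshold_used` (um), `duration` (minutes).
#' @export
migration_metrics <- function(track, threshold = 50, cell_diameter = NULL) {
  track <- as.data.frame(track)
  if (nrow(track) < 2L) stop("track needs at least 2 samples", call. = FALSE)
  if (is.unsorted(track$t, strictly = TRUE)) {
    stop("track times must be strictly increasing", call. = FALSE)
  }
  dx <- track$x - track$x[1]
  dy <- track$y - track$y[1]
  disp <- sqrt(dx^2 + dy^2)
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  duration <- track$t[nrow(track)] - track$t[1]
  thr <- if (is.null(cell_diameter)) threshold else 2 * cell_diameter
  list(max_displacement = max(disp),
       path_length = sum(steps),
       mean_speed = sum(steps) / (duration / 60),
       migrating = max(disp) > thr,
       threshold_used = thr,
       duration = duration)
}

#' Percent of migrating cells
#'
#' Fraction of tracks classified migrating (maximum displacement strictly
#' greater than `threshold`), as a percentage. Tracks covering less than
#' `min_coverage` of the movie duration (the longest track span) are
#' excluded, so cells that drift out of frame early do not dilute the
#' denominator.
#'
#' @param tracks Long-format tracks data.frame (`cell`, `t`, `x`, `y`),
#'   optionally with a `movie` column for per-movie grouping.
#' @param threshold Migration threshold, um.
#' @param min_coverage Minimum track span as a fraction of the movie span.
#'
#' @return List: `percent`, `n_migrating`, `n_total`; if a `movie` column is
#'   present, also `per_movie` (data.frame).
#' @export
percent_migrating <- function(tracks, threshold = 50, min_coverage = 0.8) {
  tracks <- as.data.frame(tracks)
  if (nrow(tracks) == 0L) stop("no tracks supplied", call. = FALSE)
  movie <- if ("movie" %in% names(tracks)) tracks$movie else rep(1L, nrow(tracks))
  one_movie <- function(tr) {
    span <- max(tr$t) - min(tr$t)
    per_cell <- split(tr, tr$cell)
    kept <- Filter(function(p) {
      nrow(p) >= 2L && (max(p$t) - min(p$t)) >= min_coverage * span
    }, per_cell)
    if (length(kept) == 0L) return(c(migrating = 0L, total = 0L))
    mig <- vapply(kept, function(p)
      migration_metrics(p, threshold = threshold)$migrating, TRUE)
    c(migrating = sum(mig), total = length(mig))
  }
  counts <- t(vapply(split(tracks, movie), one_movie, c(migrating = 0L, total = 0L)))
  n_mig <- sum(counts[, "migrating"]); n_tot <- sum(counts[, "total"])
  if (n_tot == 0L) stop("no track satisfies the coverage requirement", call. = FALSE)
  out <- list(percent = 100 * n_mig / n_tot, n_migrating = n_mig,
              n_total = n_tot)
  if ("movie" %in% names(tracks)) {
    out$per_movie <- data.frame(movie = rownames(counts),
                                n_migrating = counts[, "migrating"],
                                n_total = counts[, "total"],
                                percent = 100 * counts[, "migrating"] /
                                  pmax(counts[, "total"], 1L))
    rownames(out$per_movie) <- NULL
  }
  out
}

#' Turn angle between two directions
#'
#' Angle of deflection between a cell's direction of travel (or morphological
#' long axis) immediately before a durotactic stimulus and its direction
#' after a fixed delay (default 75 minutes), in degrees within `[0, 180]`.
#'
#' @param before,after Non-zero 2-vectors (any length units).
#' @param evaluation_delay Delay between the two measurements, minutes
#'   (recorded, not used in the computation).
#' @param source Free-text record of where the directions came from
#'   (`"track"`, `"long-axis"`, ...).
#'
#' @return List: `theta` (degrees), `direction_before`, `direction_after`
#'   (unit vectors), `evaluation_delay`, `source`.
#' @export
turn_angle <- function(before, after, evaluation_delay = 75,
                       source = "track") {
  nb <- sqrt(sum(before^2)); na <- sqrt(sum(after^2))
  if (nb == 0 || na == 0) {
    stop("direction vectors must be non-zero", call. = FALSE)
  }
  ub <- before / nb; ua <- after / na
  ct <- max(min(sum(ub * ua), 1), -1)
  list(theta = acos(ct) * 180 / pi, direction_before = ub,
       direction_after = ua, evaluation_delay = evaluation_delay,
       source = source)
}

#' Track tangent direction near a time point
#'
#' Average step direction over a smoothing window of frames ending at (or
#' starting from) `at_time`, used to extract the before/after directions for
#' [turn_angle()] from tracks.
#'
#' @param track Track data.frame (`t`, `x`, `y`).
#' @param at_time Time, minutes.
#' @param window Number of frames averaged (default 3).
#' @param side `"before"` (steps ending at `at_time`) or `"after"`.
#'
#' @return Length-2 direction vector (not normalized).
#' @export
track_direction <- function(track, at_time, window = 3L,
                            side = c("before", "after")) {
  side <- match.arg(side)
  track <- as.data.frame(track)
  i <- which.min(abs(track$t - at_time))
  idx <- if (side == "before") max(1L, i - window):i else i:min(nrow(track), i + window)
  if (length(idx) < 2L) stop("not enough samples around `at_time`", call. = FALSE)
  c(track$x[idx[length(idx)]] - track$x[idx[1]],
    track$y[idx[length(idx)]] - track$y[idx[1]])
}

#' Temporal color-coded projection of tracks
#'
#' Renders cell positions into an RGB image with frame index mapped onto a
#' perceptually ordered colormap and combined by maximum projection, the
#' standard visualization of cumulative cell tracks over a time-lapse movie.
#'
#' @param tracks Tracks data.frame (`cell`, `t`, `x`, `y`) with positions in
#'   px, or a list of image matrices (a stack) to project directly.
#' @param image_size `c(rows, cols)` of the canvas (tracks input only).
#' @param radius Dot radius, px.
#' @param palette Color vector ordered by time.
#'
#' @return `rows x cols x 3` RGB array, values in 0..1.
#' @export
color_coded_projection <- function(tracks, image_size = c(512L, 512L),
                                   radius = 2,
                                   palette = grDevices::hcl.colors(64, "plasma")) {
  rgbpal <- t(grDevices::col2rgb(palette)) / 255
  if (is.list(tracks) && !is.data.frame(tracks)) {
    if (length(tracks) == 0L) stop("empty stack", call. = FALSE)
    dims <- dim(tracks[[1]])
    out <- array(0, c(dims, 3L))
    nfr <- length(tracks)
    for (f in seq_len(nfr)) {
      col <- rgbpal[1L + floor((f - 1) / max(nfr - 1, 1) * (nrow(rgbpal) - 1L)), ]
      fr <- tracks[[f]] / max(max(tracks[[f]]), .Machine$double.eps)
      for (ch in 1:3) out[, , ch] <- pmax(out[, , ch], fr * col[ch])
    }
    return(out)
  }
  tracks <- as.data.frame(tracks)
  if (nrow(tracks) == 0L) stop("empty track set", call. = FALSE)
  times <- sort(unique(tracks$t))
  if (length(times) < 2L) stop("need at least 2 frames", call. = FALSE)
  out <- array(0, c(image_size, 3L))
  off <- expand.grid(dr = -ceiling(radius):ceiling(radius),
                     dc = -ceiling(radius):ceiling(radius))
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  for (k in seq_len(nrow(tracks))) {
    f <- match(tracks$t[k], times)
    col <- rgbpal[1L + floor((f - 1) / (length(times) - 1) * (nrow(rgbpal) - 1L)), ]
    r <- round(tracks$y[k]) + off$dr
    c <- round(tracks$x[k]) + off$dc
    ok <- r >= 1 & r <= image_size[1] & c >= 1 & c <= image_size[2]
    for (ch in 1:3) {
      idx <- cbind(r[ok], c[ok], ch)
      out[idx] <- pmax(out[idx], col[ch])
    }
  }
  out
}
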