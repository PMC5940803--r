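# Spheroid footprint segmentation and disaggregation quantification.

#' Segment a spheroid footprint
#'
#' Outlines the footprint of a multicellular aggregate in a phase-contrast
#' image. Two automatic methods are provided: `"intensity"` (default)
#' thresholds the smoothed absolute deviation from the background level
#' (median of the image border) with Otsu's method; `"texture"` thresholds a
#' local standard-deviation map instead, for images where the aggregate
#' differs from background mainly in texture. Both are followed by
#' morphological closing, hole filling, and a size filter. At the initial
#' timepoint the largest component is kept; for disaggregated late
#' timepoints use `mode = "union"` so dispersed fragments count toward the
#' footprint. A manually outlined polygon may be supplied instead of an
#' automatic method.
#'
#' @param image Single-channel image matrix.
#' @param method `"intensity"`, `"texture"`, or a two-column polygon matrix
#'   of `(x, y)` vertices (manual outline).
#' @param mode `"largest"` (single component) or `"union"` (all components
#'   above `min_area`); `"hull"` takes the convex hull of the union.
#' @param min_area Minimum component area, px^2.
#' @param pixel_size Pixel size, um (1 = report areas in px^2).
#' @param smooth Gaussian smoothing sigma, px.
#' @param timepoint Acquisition time, hours (metadata).
#'
#' @return A `spheroid_observation`: `mask` (logical matrix), `area`
#'   (um^2, or px^2 when `pixel_size = 1`), `timepoint`, `pixel_size`,
#'   `method`, `mode`.
#' @export
segment_spheroid <- function(image, method = "intensity",
                             mode = c("largest", "union", "hull"),
                             min_area = 200, pixel_size = 1, smooth = 1,
                             timepoint = NA_real_) {
  stopifnot(is.matrix(image))
  mode <- match.arg(mode)
  nr <- nrow(image); nc <- ncol(image)
  if (is.matrix(method) && ncol(method) == 2L) {
    gx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    gy <- matrix(seq_len(nr), nr, nc)
    mask <- matrix(pracma::inpolygon(as.vector(gx), as.vector(gy),
                                     method[, 1], method[, 2],
                                     boundary = TRUE), nr, nc)
    method_name <- "manual"
  } else {
    method_name <- match.arg(method, c("intensity", "texture"))
    img <- if (smooth > 0) as.matrix(EBImage::gblur(image, sigma = smooth)) else image
    if (method_name == "intensity") {
      border <- c(img[1:2, ], img[(nr - 1):nr, ], img[, 1:2], img[, (nc - 1):nc])
      feat <- abs(img - stats::median(border))
    } else {
      k <- matrix(1 / 25, 5, 5)
      m1 <- as.matrix(EBImage::filter2(img, k))
      m2 <- as.matrix(EBImage::filter2(img^2, k))
      feat <- sqrt(pmax(m2 - m1^2, 0))
    }
    thr <- otsu_threshold(feat)
    if (max(feat) <= 0 || sum(feat > thr) < min_area) {
      stop("spheroid segmentation failed: no aggregate found above threshold",
           call. = FALSE)
    }
    mask <- feat > thr
    brush <- EBImage::makeBrush(5, "disc")
    mask <- as.matrix(EBImage::closing(matrix(as.numeric(mask), nr, nc), brush)) > 0.5
    mask <- as.matrix(EBImage::fillHull(matrix(as.numeric(mask), nr, nc))) > 0.5
  }
  labels <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask), nr, nc)))
  nlab <- max(labels)
  if (nlab == 0L) {
    stop("spheroid segmentation failed: empty mask", call. = FALSE)
  }
  sizes <- tabulate(labels[labels > 0L], nbins = nlab)
  keep <- if (mode == "largest") which.max(sizes) else which(sizes >= min_area)
  if (length(keep) == 0L) keep <- which.max(sizes)
  mask <- matrix(labels %in% keep, nr, nc)
  if (sum(mask) < min_area) {
    stop("spheroid segmentation failed: largest component below minimum size",
         call. = FALSE)
  }
  if (mode == "hull") {
    pts <- which(mask, arr.ind = TRUE)
    h <- grDevices::chull(pts[, 2], pts[, 1])
    gx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    gy <- matrix(seq_len(nr), nr, nc)
    mask <- matrix(pracma::inpolygon(as.vector(gx), as.vector(gy),
                                     pts[h, 2], pts[h, 1], boundary = TRUE),
                   nr, nc)
  }
  structure(list(mask = mask, area = sum(mask) * pixel_size^2,
                 timepoint = timepoint, pixel_size = pixel_size,
                 method = method_name, mode = mode),
            class = "spheroid_observation")
}

#' @export
print.spheroid_observation <- function(x, ...) {
  cat(sprintf("<spheroid_observation> t = %g h, area %.4g (%s, %s)\n",
              x$timepoint, x$area, x$method, x$mode))
  invisible(x)
}

#' Spheroid disaggregation fold-change
#'
#' Degree of dispersion quantified as the footprint area at the final
#' timepoint (typically 20 h) divided by the area at the initial timepoint
#' (typically 2 h). With `relative = TRUE` the result also carries each
#' observation normalized to the initial area (relative-area mode).
#'
#' @param obs_initial,obs_final `spheroid_observation`s with the same pixel
#'   size.
#' @param relative Also return the relative-area series.
#'
#' @return A `disaggregation_result`: `area_initial`, `area_final`,
#'   `fold_change`, and optionally `relative_series`.
#' @export
disaggregation_fold <- function(obs_initial, obs_final, relative = FALSE) {
  stopifnot(inherits(obs_initial, "spheroid_observation"),
            inherits(obs_final, "spheroid_observation"))
  if (obs_initial$pixel_size != obs_final$pixel_size) {
    stop("observations have different pixel sizes", call. = FALSE)
  }
  if (obs_initial$area <= 0) stop("initial area is zero", call. = FALSE)
  out <- list(area_initial = obs_initial$area, area_final = obs_final$area,
              fold_change = obs_final$area / obs_initial$area)
  if (relative) {
    out$relative_series <- c(initial = 1,
                             final = obs_final$area / obs_initial$area)
  }
  structure(out, class = "disaggregation_result")
}

#' @export
print.disaggregation_result <- function(x, ...) {
  cat(sprintf("<disaggregation_result> %.4g -> %.4g (fold %.3g)\n",
              x$area_initial, x$area_final, x$fold_change))
  invisible(x)
}
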