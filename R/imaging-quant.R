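# Fluorescence-image quantifications: cell area, focal-adhesion morphometry,
# colocalization, linescans, nuclear:cytoplasmic ratios.

# Ellipse aspect ratio (major/minor) of a pixel set from the eigenvalues of
# its coordinate covariance; 1 for degenerate (< 3 px) sets.
pixel_aspect_ratio <- function(rows, cols) {
  if (length(rows) < 3L) return(1)
  cv <- stats::cov(cbind(rows, cols))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Cell area from a cytoskeletal stain
#'
#' Binary mask by thresholding a phalloidin (F-actin) image, hole filling,
#' and keeping the largest connected component; the area is the mask pixel
#' count times the pixel area. If more than one sizeable component is
#' present, `multiple_cells` is flagged.
#'
#' @param image Single-channel image matrix.
#' @param threshold `"otsu"` or a numeric cutoff.
#' @param pixel_size Pixel size, um.
#' @param min_area Minimum component size, px^2, for the multiple-cell flag.
#'
#' @return A `cell_mask`: `mask`, `area` (um^2), `pixel_size`,
#'   `multiple_cells` flag.
#' @export
cell_area <- function(image, threshold = "otsu", pixel_size = 0.1075,
                      min_area = 100) {
  stopifnot(is.matrix(image))
  thr <- if (identical(threshold, "otsu")) otsu_threshold(image) else threshold
  mask <- image > thr
  if (!any(mask)) stop("cell segmentation failed: empty mask", call. = FALSE)
  m <- matrix(as.numeric(mask), nrow(image), ncol(image))
  m <- as.matrix(EBImage::fillHull(m))
  labels <- as.matrix(EBImage::bwlabel(m))
  sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
  multiple <- sum(sizes >= min_area) > 1L
  mask <- matrix(labels == which.max(sizes), nrow(image), ncol(image))
  structure(list(mask = mask, area = sum(mask) * pixel_size^2,
                 pixel_size = pixel_size, multiple_cells = multiple),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> area %.4g um^2%s\n", x$area,
              if (x$multiple_cells) " (multiple cells flagged)" else ""))
  invisible(x)
}

#' Segment focal adhesions
#'
#' Outlines individual focal adhesions by thresholding an adhesion-marker
#' channel (vinculin, paxillin, pFAK) after constant background subtraction,
#' keeping connected components above a minimum size. Per adhesion the area,
#' best-fit-ellipse aspect ratio, centroid and pixel indices are returned, so
#' the same ROIs can be transferred to other raw channels.
#'
#' @param image Adhesion-channel image matrix.
#' @param cell_mask Optional logical matrix restricting the search.
#' @param min_area Minimum adhesion area, um^2 (default 0.25).
#' @param pixel_size Pixel size, um.
#' @param threshold `"otsu"` or numeric cutoff applied after background
#'   subtraction.
#'
#' @return data.frame with one row per adhesion: `label`, `area` (um^2),
#'   `aspect_ratio`, `x`, `y` (centroid, px), `mean_intensity`; the pixel
#'   index sets are attached as attribute `pixels` (list of integer vectors
#'   indexing the image). Zero rows when nothing is found.
#' @export
segment_adhesions <- function(image, cell_mask = NULL, min_area = 0.25,
                              pixel_size = 0.1075, threshold = "otsu") {
  stopifnot(is.matrix(image))
  region <- if (is.null(cell_mask)) matrix(TRUE, nrow(image), ncol(image))
            else cell_mask
  vals <- image[region]
  bg <- stats::median(vals)
  work <- pmax(image - bg, 0)
  work[!region] <- 0
  empty <- data.frame(label = integer(0), area = numeric(0),
                      aspect_ratio = numeric(0), x = numeric(0),
                      y = numeric(0), mean_intensity = numeric(0))
  attr(empty, "pixels") <- list()
  if (max(work) <= 0) return(empty)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(work[region])
         else threshold
  mask <- work > thr
  if (!any(mask)) return(empty)
  labels <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask),
                                              nrow(image), ncol(image))))
  nlab <- max(labels)
  min_px <- max(1L, round(min_area / pixel_size^2))
  sizes <- tabulate(labels[labels > 0L], nbins = nlab)
  keep <- which(sizes >= min_px)
  if (length(keep) == 0L) return(empty)
  rows <- lapply(seq_along(keep), function(k) {
    pix <- which(labels == keep[k])
    rc <- arrayInd(pix, dim(image))
    data.frame(label = k, area = length(pix) * pixel_size^2,
               aspect_ratio = pixel_aspect_ratio(rc[, 1], rc[, 2]),
               x = mean(rc[, 2]), y = mean(rc[, 1]),
               mean_intensity = mean(image[pix]))
  })
  out <- do.call(rbind, rows)
  attr(out, "pixels") <- lapply(keep, function(k) which(labels == k))
  out
}

#' Per-adhesion intensity ratio between two channels
#'
#' For each adhesion ROI, the mean intensity in the numerator channel divided
#' by the mean intensity in the denominator channel (e.g. pFAK normalized to
#' vinculin within each adhesion). ROIs with a non-positive denominator mean
#' are flagged and excluded.
#'
#' @param rois Output of [segment_adhesions()] (must carry the `pixels`
#'   attribute).
#' @param numerator,denominator Image matrices co-registered with the ROI
#'   frame.
#' @param breaks Histogram breaks for the ratio distribution (number or
#'   vector, as in [hist()]).
#'
#' @return List: `ratios` (data.frame `label`, `ratio`, `excluded`),
#'   `histogram` (a `histogram` object over the kept ratios, `NULL` if none).
#' @export
adhesion_intensity_ratio <- function(rois, numerator, denominator,
                                     breaks = "Sturges") {
  pixels <- attr(rois, "pixels")
  if (is.null(pixels)) stop("`rois` lacks the pixels attribute", call. = FALSE)
  stopifnot(all(dim(numerator) == dim(denominator)))
  ratio <- excluded <- numeric(0)
  if (length(pixels)) {
    num <- vapply(pixels, function(p) mean(numerator[p]), 0)
    den <- vapply(pixels, function(p) mean(denominator[p]), 0)
    excluded <- den <= 0
    ratio <- ifelse(excluded, NA_real_, num / den)
  }
  kept <- ratio[is.finite(ratio)]
  list(ratios = data.frame(label = rois$label, ratio = ratio,
                           excluded = as.logical(excluded)),
       histogram = if (length(kept)) graphics::hist(kept, breaks = breaks,
                                                    plot = FALSE) else NULL)
}

#' Manders colocalization coefficients
#'
#' Standard Manders split coefficients: `M1` is the fraction of channel A
#' intensity found in pixels where channel B exceeds its threshold, and
#' symmetrically for `M2`. Pearson correlation is also reported over the
#' joint mask (pixels above threshold in either channel). Thresholds default
#' to 0 (the classical definition); `auto = TRUE` estimates Costes-style
#' thresholds by lowering a common quantile until the below-threshold pixels
#' are uncorrelated.
#'
#' @param channel_a,channel_b Same-shape non-negative image matrices.
#' @param threshold_a,threshold_b Intensity thresholds (>= 0).
#' @param auto Use automatic (Costes-style) thresholds instead.
#'
#' @return A `coloc_result`: `manders_m1`, `manders_m2`, `pearson_r`,
#'   `threshold_a`, `threshold_b`.
#' @export
manders <- function(channel_a, channel_b, threshold_a = 0, threshold_b = 0,
                    auto = FALSE) {
  stopifnot(is.matrix(channel_a), all(dim(channel_a) == dim(channel_b)))
  if (sum(channel_a) <= 0 || sum(channel_b) <= 0) {
    stop("colocalization undefined: a channel is all zero", call. = FALSE)
  }
  if (auto) {
    thr <- costes_thresholds(channel_a, channel_b)
    threshold_a <- thr[1]; threshold_b <- thr[2]
  }
  m1 <- sum(channel_a[channel_b > threshold_b]) / sum(channel_a)
  m2 <- sum(channel_b[channel_a > threshold_a]) / sum(channel_b)
  joint <- channel_a > threshold_a | channel_b > threshold_b
  r <- if (sum(joint) >= 3L &&
           stats::sd(channel_a[joint]) > 0 && stats::sd(channel_b[joint]) > 0) {
    stats::cor(channel_a[joint], channel_b[joint])
  } else NA_real_
  structure(list(manders_m1 = m1, manders_m2 = m2, pearson_r = r,
                 threshold_a = threshold_a, threshold_b = threshold_b),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> M1 = %.3f, M2 = %.3f, r = %.3f\n",
              x$manders_m1, x$manders_m2, x$pearson_r))
  invisible(x)
}

# Costes-style automatic thresholds: walk a common quantile of both channels
# downward until the correlation of the strictly-below-threshold pixels drops
# to <= 0.
costes_thresholds <- function(a, b, n_steps = 50L) {
  qs <- seq(0.98, 0, length.out = n_steps)
  ta <- stats::quantile(a, qs, names = FALSE)
  tb <- stats::quantile(b, qs, names = FALSE)
  for (i in seq_len(n_steps)) {
    below <- a < ta[i] & b < tb[i]
    if (sum(below) < 10L) next
    if (stats::sd(a[below]) == 0 || stats::sd(b[below]) == 0) next
    if (stats::cor(a[below], b[below]) <= 0) return(c(ta[i], tb[i]))
  }
  c(ta[n_steps], tb[n_steps])
}

#' Intensity profile along a line
#'
#' Samples an image along the segment from `p0` to `p1` (bilinear
#' interpolation), averaging over `width` parallel lines perpendicular to
#' the segment — the ImageJ-style linescan.
#'
#' @param image Image matrix.
#' @param p0,p1 Segment endpoints `c(x, y)` in px (inside the image).
#' @param width Averaging width, px (odd integer recommended).
#' @param n Number of samples (default: ceiling of the segment length).
#'
#' @return Numeric intensity profile of length `n`.
#' @export
linescan <- function(image, p0, p1, width = 1L, n = NULL) {
  stopifnot(is.matrix(image), length(p0) == 2L, length(p1) == 2L)
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate linescan segment", call. = FALSE)
  if (is.null(n)) n <- max(2L, ceiling(len))
  u <- v / len
  perp <- c(-u[2], u[1])
  s <- seq(0, 1, length.out = n)
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(width, 1L))
  prof <- numeric(n)
  for (o in offsets) {
    x <- p0[1] + s * v[1] + o * perp[1]
    y <- p0[2] + s * v[2] + o * perp[2]
    prof <- prof + bilinear_at(image, y, x)
  }
  prof / length(offsets)
}

#' Pearson correlation of two linescan profiles
#'
#' @param profile_a,profile_b Equal-length numeric profiles.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_linescan <- function(profile_a, profile_b) {
  stopifnot(length(profile_a) == length(profile_b), length(profile_a) >= 3L)
  stats::cor(profile_a, profile_b)
}

#' Nuclear to cytoplasmic intensity ratio
#'
#' Mean signal (e.g. YAP1 immunofluorescence) inside the nuclear mask divided
#' by the mean over the cytoplasm, where the cytoplasm is the cell mask minus
#' the nuclear mask dilated by `exclusion_margin` pixels (to avoid
#' nuclear-envelope bleed-through).
#'
#' @param signal Image matrix.
#' @param nuclear_mask,cell_mask Logical matrices; the nucleus must lie
#'   inside the cell.
#' @param exclusion_margin Dilation margin, px (default 2).
#'
#' @return A `nuc_cyto_result`: `nuclear_mean`, `cytoplasmic_mean`, `ratio`,
#'   `n_nuclear_px`, `n_cyto_px`.
#' @export
nuc_cyto_ratio <- function(signal, nuclear_mask, cell_mask,
                           exclusion_margin = 2L) {
  stopifnot(is.matrix(signal), all(dim(nuclear_mask) == dim(signal)),
            all(dim(cell_mask) == dim(signal)))
  nuclear_mask <- nuclear_mask > 0
  cell_mask <- cell_mask > 0
  if (!all(cell_mask[nuclear_mask])) {
    stop("nuclear mask must lie inside the cell mask", call. = FALSE)
  }
  dilated <- nuclear_mask
  if (exclusion_margin > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(exclusion_margin) + 1L, "disc")
    dilated <- as.matrix(EBImage::dilate(matrix(as.numeric(nuclear_mask),
                                                nrow(signal), ncol(signal)),
                                         brush)) > 0.5
  }
  cyto <- cell_mask & !dilated
  if (!any(cyto)) stop("empty cytoplasm after exclusion margin", call. = FALSE)
  if (!any(nuclear_mask)) stop("empty nuclear mask", call. = FALSE)
  nm <- mean(signal[nuclear_mask])
  cm <- mean(signal[cyto])
  structure(list(nuclear_mean = nm, cytoplasmic_mean = cm, ratio = nm / cm,
                 n_nuclear_px = sum(nuclear_mask), n_cyto_px = sum(cyto)),
            class = "nuc_cyto_result")
}

#' @export
print.nuc_cyto_result <- function(x, ...) {
  cat(sprintf("<nuc_cyto_result> N:C = %.3f (nuc %.3g, cyto %.3g)\n",
              x$ratio, x$nuclear_mean, x$cytoplasmic_mean))
  invisible(x)
}
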