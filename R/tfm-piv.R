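# Block-matching particle image velocimetry and translation registration.
#
# Convention: images are matrices [row = y downward, col = x rightward],
# pixel-centred, 1-based.  Displacements are (ux, uy) = (dcol, drow) in px,
# defined as deformed = reference moved by +u.

# Fast zero-normalized cross-correlation of template t (w x w) against search
# region s (W x W), W >= w.  Returns the NCC map over offsets 0..(W-w) (the
# positions where the template fits entirely), computed via FFT plus integral
# images (the Lewis fast-NCC construction).
ncc_map <- function(t, s) {
  w <- nrow(t); W <- nrow(s)
  t0 <- t - mean(t)
  norm_t <- sqrt(sum(t0^2))
  Tpad <- pad_to(t0, W, W)
  cc <- Re(stats::fft(Conj(stats::fft(Tpad)) * stats::fft(s), inverse = TRUE)) / (W * W)
  nval <- W - w + 1L
  cc <- cc[seq_len(nval), seq_len(nval)]
  # windowed sums of s and s^2 via padded cumulative sums
  I1 <- apply(apply(s, 2, cumsum), 1, cumsum)        # transposed integral image
  I1 <- t(I1); I1 <- rbind(0, cbind(0, I1))
  I2 <- apply(apply(s^2, 2, cumsum), 1, cumsum)
  I2 <- t(I2); I2 <- rbind(0, cbind(0, I2))
  idx <- seq_len(nval)
  win_sum <- function(I) {
    I[idx + w, idx + w] - I[idx, idx + w] - I[idx + w, idx] + I[idx, idx]
  }
  S1 <- win_sum(I1); S2 <- win_sum(I2)
  var_s <- pmax(S2 - S1^2 / (w * w), 0)
  denom <- norm_t * sqrt(var_s)
  out <- matrix(0, nval, nval)
  ok <- denom > .Machine$double.eps * max(denom, 1)
  out[ok] <- cc[ok] / denom[ok]
  pmin(pmax(out, -1), 1)
}

# Subpixel localization of the correlation peak by a three-point Gaussian fit
# (falls back to parabolic when values are not all positive).
subpixel_peak <- function(cmap) {
  ij <- which(cmap == max(cmap), arr.ind = TRUE)[1, ]
  r <- ij[1]; c <- ij[2]
  # a perfect correlation is an exact lattice match; refinement would only
  # add asymmetry noise from the surrounding pixels
  if (cmap[r, c] >= 1 - 1e-9) {
    return(list(row = as.numeric(r), col = as.numeric(c), score = cmap[r, c]))
  }
  refine <- function(cm1, c0, cp1) {
    if (cm1 > 0 && c0 > 0 && cp1 > 0) {
      l1 <- log(cm1); l0 <- log(c0); l2 <- log(cp1)
      den <- l1 - 2 * l0 + l2
      if (den < 0) return((l1 - l2) / (2 * den))
    }
    den <- cm1 - 2 * c0 + cp1
    if (den < 0) (cm1 - cp1) / (2 * den) else 0
  }
  dr <- if (r > 1 && r < nrow(cmap))
    refine(cmap[r - 1, c], cmap[r, c], cmap[r + 1, c]) else 0
  dc <- if (c > 1 && c < ncol(cmap))
    refine(cmap[r, c - 1], cmap[r, c], cmap[r, c + 1]) else 0
  list(row = r + max(min(dr, 0.5), -0.5), col = c + max(min(dc, 0.5), -0.5),
       score = cmap[r, c])
}

#' Register an image stack by translation
#'
#' Removes bulk drift from an image sequence by whole-frame cross-correlation
#' against a reference frame, with subpixel peak refinement. The recovered
#' shifts can be applied to companion images (e.g. the phase-contrast channel
#' acquired alongside the beads) with [apply_shifts()].
#'
#' @param stack List of matrices (frames), all the same shape.
#' @param reference_index Index of the reference frame (default 1).
#' @param min_confidence Peak correlation below which a frame is flagged
#'   low-confidence and left unshifted.
#'
#' @return List: `stack` (registered frames), `shifts` (n x 2 matrix of
#'   (drow, dcol) recovered per frame, px), `confidence` (peak normalized
#'   correlation per frame), `low_confidence` (logical).
#' @export
register_translation <- function(stack, reference_index = 1L,
                                 min_confidence = 0.1) {
  stopifnot(is.list(stack), length(stack) >= 2L)
  dims <- dim(stack[[1]])
  stopifnot(all(vapply(stack, function(f) all(dim(f) == dims), TRUE)))
  ref <- stack[[reference_index]]
  ref0 <- ref - mean(ref)
  Fref <- stats::fft(ref0)
  nr <- dims[1]; nc <- dims[2]
  shifts <- matrix(0, length(stack), 2L,
                   dimnames = list(NULL, c("drow", "dcol")))
  confidence <- numeric(length(stack))
  out <- stack
  norm_ref <- sqrt(sum(ref0^2))
  for (i in seq_along(stack)) {
    if (i == reference_index) { confidence[i] <- 1; next }
    fr <- stack[[i]] - mean(stack[[i]])
    cc <- Re(stats::fft(Conj(Fref) * stats::fft(fr), inverse = TRUE)) / (nr * nc)
    denom <- norm_ref * sqrt(sum(fr^2))
    cmap <- if (denom > 0) cc / denom else cc * 0
    # fftshift so the zero-offset peak sits mid-array and subpixel
    # refinement has neighbours on both sides
    hr <- nr %/% 2L; hc <- nc %/% 2L
    cmap <- cmap[c((hr + 1L):nr, 1L:hr), c((hc + 1L):nc, 1L:hc)]
    pk <- subpixel_peak(cmap)
    dr <- pk$row - (nr - hr + 1L)
    dc <- pk$col - (nc - hc + 1L)
    confidence[i] <- pk$score
    if (pk$score < min_confidence) { shifts[i, ] <- 0; next }
    shifts[i, ] <- c(dr, dc)
    out[[i]] <- shift_image(stack[[i]], -dr, -dc)
  }
  list(stack = out, shifts = shifts, confidence = confidence,
       low_confidence = confidence < min_confidence)
}

#' Apply registration shifts to a companion stack
#'
#' @param stack List of matrices matching the stack passed to
#'   [register_translation()].
#' @param shifts The `shifts` matrix returned by [register_translation()].
#' @return List of shifted frames.
#' @export
apply_shifts <- function(stack, shifts) {
  stopifnot(length(stack) == nrow(shifts))
  lapply(seq_along(stack), function(i)
    shift_image(stack[[i]], -shifts[i, 1], -shifts[i, 2]))
}

#' Multi-pass PIV displacement estimation
#'
#' Estimates the displacement field between a reference (zero-force) and a
#' deformed bead image by iterative normalized cross-correlation block
#' matching. Each pass halves the interrogation window, search window, and
#' vector spacing of the previous one (default first pass 128/256/64 px,
#' three passes) and offsets the search windows by the displacement predicted
#' from the previous pass. Vectors whose correlation peak falls below
#' `corr_min` are invalidated and replaced by the median of their valid
#' neighbours. Peak positions are refined to subpixel precision by a
#' three-point Gaussian fit.
#'
#' @param reference,deformed Same-shape image matrices.
#' @param window,search,spacing First-pass interrogation window, search
#'   window, and vector spacing, px (powers of two recommended).
#' @param passes Number of passes (parameters halve each pass).
#' @param corr_min Correlation validity threshold (default 0.8).
#' @param pixel_size Pixel size, um, carried into the output field.
#'
#' @return A [displacement_field()] in px on the final-pass grid; `valid`
#'   flags vectors that met `corr_min` before neighbour interpolation.
#' @export
piv_multipass <- function(reference, deformed, window = 128L, search = 256L,
                          spacing = 64L, passes = 3L, corr_min = 0.8,
                          pixel_size = 0.161) {
  stopifnot(is.matrix(reference), is.matrix(deformed),
            all(dim(reference) == dim(deformed)))
  nr <- nrow(reference); nc <- ncol(reference)
  if (search > min(nr, nc)) {
    stop("image smaller than the first-pass search window", call. = FALSE)
  }
  prev <- NULL
  for (p in seq_len(passes)) {
    f <- 2^(p - 1)
    w <- as.integer(window / f); W <- as.integer(search / f)
    sp <- as.integer(spacing / f)
    if (w < 8L || sp < 1L) break
    half_w <- w %/% 2L; half_W <- W %/% 2L
    centers_r <- seq(half_W + 1L, nr - half_W + 1L, by = sp)
    centers_c <- seq(half_W + 1L, nc - half_W + 1L, by = sp)
    ngr <- length(centers_r); ngc <- length(centers_c)
    if (ngr < 2L || ngc < 2L) {
      stop("image too small for the requested PIV grid", call. = FALSE)
    }
    ux <- uy <- corr <- matrix(0, ngr, ngc)
    # predicted displacement at the new grid, from the previous pass
    if (!is.null(prev)) {
      pr <- (centers_r - prev$origin[1]) / prev$spacing + 1
      pc <- (centers_c - prev$origin[2]) / prev$spacing + 1
      PR <- as.vector(matrix(pr, ngr, ngc))
      PC <- as.vector(matrix(pc, ngr, ngc, byrow = TRUE))
      pred_x <- round(matrix(bilinear_at(prev$ux, PR, PC), ngr, ngc))
      pred_y <- round(matrix(bilinear_at(prev$uy, PR, PC), ngr, ngc))
    } else {
      pred_x <- pred_y <- matrix(0, ngr, ngc)
    }
    margin <- (W - w) %/% 2L
    for (i in seq_len(ngr)) {
      for (j in seq_len(ngc)) {
        cr <- centers_r[i]; cc <- centers_c[j]
        tpl <- reference[(cr - half_w):(cr + half_w - 1L),
                         (cc - half_w):(cc + half_w - 1L)]
        # offset the search window by the (clamped) integer prediction
        ox <- min(max(pred_x[i, j], -(cc - half_W - 1L)), nc - (cc + half_W - 1L))
        oy <- min(max(pred_y[i, j], -(cr - half_W - 1L)), nr - (cr + half_W - 1L))
        srch <- deformed[(cr + oy - half_W):(cr + oy + half_W - 1L),
                         (cc + ox - half_W):(cc + ox + half_W - 1L)]
        cmap <- ncc_map(tpl, srch)
        pk <- subpixel_peak(cmap)
        uy[i, j] <- (pk$row - 1 - margin) + oy
        ux[i, j] <- (pk$col - 1 - margin) + ox
        corr[i, j] <- pk$score
      }
    }
    valid <- corr >= corr_min
    field <- displacement_field(ux, uy, spacing = sp, units = "px",
                                pixel_size = pixel_size, correlation = corr,
                                valid = valid,
                                origin = c(centers_r[1], centers_c[1]))
    if (!any(valid)) {
      stop("PIV failed: no vector reached the correlation threshold", call. = FALSE)
    }
    filled <- fill_invalid_vectors(field)
    filled$valid <- valid            # keep the pre-interpolation flags
    prev <- filled
  }
  prev
}
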