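#' AFM force-indentation curve
#'
#' Container for a single atomic force microscopy approach curve. Either a
#' force channel (nN) or a raw cantilever deflection channel (um) plus a
#' spring constant (N/m) may be supplied; in the latter case force is derived
#' once as `force[nN] = 1000 * spring_constant[N/m] * deflection[um]`.
#'
#' @param z Piezo extension positions, um, monotone increasing on approach.
#' @param force Force channel, nN. Exactly one of `force`/`deflection`.
#' @param deflection Raw cantilever deflection, um.
#' @param probe_radius Probe sphere radius, um (default 2.5, a 5 um sphere).
#' @param poisson Sample Poisson ratio (default 0.5, incompressible).
#' @param spring_constant Cantilever spring constant, N/m (default 0.06).
#' @param metadata Optional named list (probe speed, retraction, ...).
#'
#' @return A `force_curve` object with fields `z` (um), `force` (nN),
#'   `probe_radius`, `poisson`, `spring_constant`, `metadata`.
#' @export
force_curve <- function(z, force = NULL, deflection = NULL,
                        probe_radius = 2.5, poisson = 0.5,
                        spring_constant = 0.06, metadata = list()) {
  stopifnot(is.numeric(z), length(z) >= 10L)
  check_scalar(probe_radius, "probe_radius", 0, strict_lower = TRUE)
  check_scalar(poisson, "poisson", 0, 0.5)
  check_scalar(spring_constant, "spring_constant", 0, strict_lower = TRUE)
  if (is.null(force)) {
    if (is.null(deflection)) stop("supply `force` or `deflection`", call. = FALSE)
    # d[um] * k[N/m] = k*d * 1e-6 N = k*d * 1e3 nN
    force <- deflection * spring_constant * 1e3
  }
  if (length(force) != length(z)) stop("`z` and `force` lengths differ", call. = FALSE)
  structure(list(z = as.numeric(z), force = as.numeric(force),
                 probe_radius = probe_radius, poisson = poisson,
                 spring_constant = spring_constant, metadata = metadata),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, z %.2f..%.2f um, Fmax %.3g nN, R = %.2f um\n",
              length(x$z), min(x$z), max(x$z), max(x$force), x$probe_radius))
  invisible(x)
}

#' Hertz contact force for a spherical indenter
#'
#' Closed-form indentation force of a rigid sphere on an elastic half-space
#' (paraboloidal approximation, valid for indentation much smaller than the
#' probe radius):
#' \deqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}}
#'
#' @param E Young's modulus, Pa.
#' @param indentation Indentation depth(s) delta, um; must be >= 0.
#' @param probe_radius Sphere radius R, um.
#' @param poisson Poisson ratio nu of the sample.
#'
#' @return Force in nN (same length as `indentation`).
#' @export
hertz_force <- function(E, indentation, probe_radius = 2.5, poisson = 0.5) {
  check_scalar(E, "E", 0, strict_lower = TRUE)
  check_scalar(probe_radius, "probe_radius", 0, strict_lower = TRUE)
  check_scalar(poisson, "poisson", 0, 0.5)
  if (any(indentation < 0)) stop("`indentation` must be >= 0", call. = FALSE)
  # E[Pa] * sqrt(R[um]) * d[um]^1.5 -> Pa * um^2 * 1e-12 = 1e-12 N = 1e-3 nN
  (4 / 3) * E / (1 - poisson^2) * sqrt(probe_radius) * indentation^1.5 * 1e-3
}

# Model force for piezo positions z with contact point cp: zero before
# contact, Hertzian beyond.
hertz_model_force <- function(z, cp, E, probe_radius, poisson) {
  delta <- pmax(z - cp, 0)
  hertz_force(E, delta, probe_radius, poisson)
}

# Closed-form least-squares E (Pa) for fixed contact point on the selected
# samples; F is linear in E.
hertz_E_given_contact <- function(z, force, cp, probe_radius, poisson) {
  g <- (4 / 3) / (1 - poisson^2) * sqrt(probe_radius) * pmax(z - cp, 0)^1.5 * 1e-3
  s2 <- sum(g^2)
  if (s2 == 0) return(NA_real_)
  max(sum(force * g) / s2, 0)
}

#' Detect the contact point of a force curve
#'
#' Estimates the piezo position at which the probe first touches the sample
#' and the pre-contact baseline force. The baseline level and noise are taken
#' from the early flat segment; the contact point is initialized at the first
#' sustained crossing of baseline + 3 standard deviations and then refined by
#' a joint two-segment (flat + Hertz) least-squares fit with the changepoint
#' as a free parameter.
#'
#' @param curve A [force_curve()].
#' @param baseline_fraction Fraction of the earliest samples assumed
#'   pre-contact for the initial baseline estimate (default 0.1).
#'
#' @return List with `contact_point` (um), `baseline` (nN), `noise_sd` (nN).
#' @export
detect_contact_point <- function(curve, baseline_fraction = 0.1) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z; f <- curve$force
  n <- length(z)
  nb <- max(5L, floor(baseline_fraction * n))
  baseline <- stats::median(f[seq_len(nb)])
  noise_sd <- stats::mad(f[seq_len(nb)])
  fmax <- max(f) - baseline
  if (fmax <= max(6 * noise_sd, .Machine$double.eps * 100)) {
    stop("no contact detected: curve is flat", call. = FALSE)
  }
  thresh <- baseline + max(3 * noise_sd, 0.01 * fmax)
  above <- f > thresh
  # first index from which the curve stays above threshold
  idx <- which(above & rev(cumprod(rev(above))) == 1)
  i0 <- if (length(idx)) idx[1] else which(above)[1]
  cp0 <- if (i0 <= 1L) z[1] else z[i0 - 1L]
  # refine: joint fit of flat baseline + Hertz segment over the whole curve
  obj <- function(cp) {
    E <- hertz_E_given_contact(z, f - baseline, cp, curve$probe_radius, curve$poisson)
    if (!is.finite(E)) return(Inf)
    pred <- hertz_model_force(z, cp, E, curve$probe_radius, curve$poisson)
    sum((f - baseline - pred)^2)
  }
  span <- diff(range(z))
  lo <- max(min(z), cp0 - 0.2 * span)
  hi <- min(max(z), cp0 + 0.2 * span)
  cp <- if (hi > lo) stats::optimize(obj, c(lo, hi))$minimum else cp0
  list(contact_point = cp, baseline = baseline, noise_sd = noise_sd)
}

#' Fit the Hertz model to a force curve
#'
#' Least-squares fit of the spherical-indenter Hertz law [hertz_force()] to an
#' approach curve. Samples whose baseline-subtracted force lies outside
#' `window` (as fractions of the curve's maximum force, default 15 to 80
#' percent) are excluded from the fit; the window is interpreted on the force
#' axis, the common AFM convention that is robust to piezo-range variation.
#' The contact point comes from the full-curve two-segment fit of
#' [detect_contact_point()], where the pre-contact baseline anchors the
#' changepoint; the modulus is then the closed-form least-squares solution on
#' the windowed samples with that contact point held fixed (re-fitting the
#' changepoint on the windowed samples alone would leave it unconstrained by
#' the baseline and would bias the modulus under noise).
#'
#' @param curve A [force_curve()].
#' @param window Length-2 numeric, lower/upper force-axis fractions in (0,1)
#'   (lower may be 0 and upper 1 to disable the exclusion).
#'
#' @return A `hertz_fit` object: `E` (Pa), `contact_point` (um),
#'   `fit_window`, `residual_rms` (nN), `n_points_used`, `converged`.
#' @export
fit_hertz <- function(curve, window = c(0.15, 0.80)) {
  stopifnot(inherits(curve, "force_curve"))
  if (length(window) != 2L || window[1] < 0 || window[2] > 1 ||
      window[1] >= window[2]) {
    stop("`window` must be increasing fractions within [0, 1]", call. = FALSE)
  }
  cd <- detect_contact_point(curve)
  z <- curve$z
  f <- curve$force - cd$baseline
  fmax <- max(f)
  sel <- f >= window[1] * fmax & f <= window[2] * fmax
  if (sum(sel) < 5L) stop("fewer than 5 samples inside the fit window", call. = FALSE)
  zs <- z[sel]; fs <- f[sel]
  cp <- cd$contact_point
  E <- hertz_E_given_contact(zs, fs, cp, curve$probe_radius, curve$poisson)
  converged <- is.finite(E) && E > 0
  pred <- hertz_model_force(zs, cp, E, curve$probe_radius, curve$poisson)
  structure(list(E = E, contact_point = cp, fit_window = window,
                 residual_rms = sqrt(mean((fs - pred)^2)),
                 n_points_used = sum(sel), converged = converged),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g kPa, contact at %.3f um, rms %.3g nN (%d pts%s)\n",
              x$E / 1e3, x$contact_point, x$residual_rms, x$n_points_used,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Assemble a force map from grid-ordered curves
#'
#' Fits every curve of one force map (by default an 8 x 8 grid covering a
#' 20 x 20 um region, 2.5 um spacing) and assembles the fitted Young's moduli
#' into a grid. Curves that fail to fit (flat, non-convergent) are flagged
#' `NA` and excluded from summaries, never silently zeroed.
#'
#' @param curves List of [force_curve()] in row-major grid order.
#' @param shape Grid dimensions, default `c(8, 8)`.
#' @param region_size Physical side length of the mapped region, um.
#' @param window Fit window passed to [fit_hertz()].
#'
#' @return A `force_map` object: `E` (matrix, Pa; `NA` where the fit failed),
#'   `region_size`, `spacing` (um), `fits` (list of `hertz_fit` or `NULL`).
#' @export
build_force_map <- function(curves, shape = c(8L, 8L), region_size = 20,
                            window = c(0.15, 0.80)) {
  n <- prod(shape)
  if (length(curves) != n) {
    stop(sprintf("expected %d curves for a %dx%d map, got %d",
                 n, shape[1], shape[2], length(curves)), call. = FALSE)
  }
  fits <- vector("list", n)
  E <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_hertz(curves[[i]], window = window), error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged)) {
      fits[[i]] <- fit
      E[i] <- fit$E
    }
  }
  structure(list(E = matrix(E, shape[1], shape[2], byrow = TRUE),
                 region_size = region_size,
                 spacing = region_size / shape[1],
                 fits = fits),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  ok <- sum(is.finite(x$E))
  cat(sprintf("<force_map> %dx%d over %g um, %d/%d fitted, median E %.3g kPa\n",
              nrow(x$E), ncol(x$E), x$region_size, ok, length(x$E),
              stats::median(x$E, na.rm = TRUE) / 1e3))
  invisible(x)
}

#' Render force maps as color-coded heat maps
#'
#' Maps moduli to a colormap either per map (`scaling = "local"`: each map
#' stretched to its own min/max) or across the whole set
#' (`scaling = "global"`: one shared min/max), mirroring the two display
#' modes used for tissue force maps. A constant map under local scaling falls
#' back to the single mid-scale color.
#'
#' @param maps A `force_map` or list of `force_map`s.
#' @param scaling `"local"` or `"global"`.
#' @param palette Color vector; default 256-step viridis.
#'
#' @return List of `nrow x ncol x 3` RGB arrays (values in 0..1), with
#'   attributes `range` (the Pa limits used) and `palette`.
#' @export
render_heatmap <- function(maps, scaling = c("local", "global"),
                           palette = grDevices::hcl.colors(256, "viridis")) {
  scaling <- match.arg(scaling)
  if (inherits(maps, "force_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "force_map")))
  vals <- unlist(lapply(maps, function(m) m$E))
  grange <- range(vals, na.rm = TRUE)
  rgb <- t(grDevices::col2rgb(palette)) / 255
  render_one <- function(m, lim) {
    E <- m$E
    out <- array(0, c(nrow(E), ncol(E), 3L))
    if (lim[2] <= lim[1]) {
      idx <- matrix(ceiling(length(palette) / 2), nrow(E), ncol(E))
    } else {
      s <- (E - lim[1]) / (lim[2] - lim[1])
      idx <- matrix(pmin(pmax(floor(s * (length(palette) - 1)) + 1L, 1L),
                         length(palette)), nrow(E), ncol(E))
    }
    for (ch in 1:3) {
      plane <- rgb[idx, ch]
      plane[!is.finite(E)] <- 0   # failed cells rendered black
      out[, , ch] <- plane
    }
    attr(out, "range") <- lim
    out
  }
  imgs <- lapply(maps, function(m) {
    lim <- if (scaling == "local") range(m$E, na.rm = TRUE) else grange
    render_one(m, lim)
  })
  attr(imgs, "scaling") <- scaling
  attr(imgs, "palette") <- palette
  imgs
}

#' Summary statistics of a modulus collection
#'
#' Order statistics of Young's moduli pooled from force maps: mean, standard
#' error of the mean, median, quartiles, extremes — the quantities shown in
#' box-and-whisker summaries of tissue and hydrogel stiffness.
#'
#' @param values Numeric vector of moduli (Pa); `NA`s (failed fits) dropped.
#'
#' @return Named list: `mean`, `sem`, `median`, `q25`, `q75`, `min`, `max`, `n`.
#' @export
summarize_moduli <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite modulus values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(mean = mean(values),
       sem = if (length(values) > 1L)
         stats::sd(values) / sqrt(length(values)) else 0,
       median = q[2], q25 = q[1], q75 = q[3],
       min = min(values), max = max(values), n = length(values))
}
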