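#' Elastic substrate description
#'
#' Physical description of a traction-force-microscopy hydrogel: Young's
#' modulus, Poisson ratio (0.5 for fully swollen polyacrylamide, the
#' incompressible limit), camera pixel size, and the dimensionless Tikhonov
#' regularization weight used by [fttc()] (see that help page for the
#' normalization).
#'
#' @param youngs_modulus Young's modulus E, Pa.
#' @param poisson Poisson ratio, in `[0, 0.5]`; default 0.5.
#' @param pixel_size Image pixel size, um; default 0.161.
#' @param lambda Dimensionless regularization weight, >= 0.
#'
#' @return An `elastic_substrate` object.
#' @export
elastic_substrate <- function(youngs_modulus, poisson = 0.5,
                              pixel_size = 0.161, lambda = 0) {
  check_scalar(youngs_modulus, "youngs_modulus", 0, strict_lower = TRUE)
  check_scalar(poisson, "poisson", 0, 0.5)
  check_scalar(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  check_scalar(lambda, "lambda", 0)
  structure(list(youngs_modulus = youngs_modulus, poisson = poisson,
                 pixel_size = pixel_size, lambda = lambda),
            class = "elastic_substrate")
}

#' @export
print.elastic_substrate <- function(x, ...) {
  cat(sprintf("<elastic_substrate> E = %g kPa, nu = %g, pixel %g um, lambda = %g\n",
              x$youngs_modulus / 1e3, x$poisson, x$pixel_size, x$lambda))
  invisible(x)
}

#' Displacement field on a regular grid
#'
#' Vector field of substrate displacements. Components are stored as matrices
#' indexed `[row, col]` with row = y (downward) and col = x (rightward),
#' pixel-centred coordinates. PIV produces fields in px; [fttc()] converts to
#' um via the spacing and pixel size.
#'
#' @param ux,uy Matrices of x/y displacement components.
#' @param spacing Grid spacing in px (distance between neighbouring vectors).
#' @param units `"px"` or `"um"` for the component values.
#' @param pixel_size Pixel size in um (used to convert px to um).
#' @param correlation Optional matrix of PIV peak correlations in `[0, 1]`.
#' @param valid Optional logical matrix flagging trustworthy vectors.
#' @param origin Image coordinates (row, col) of grid point `[1, 1]`.
#'
#' @return A `displacement_field` object.
#' @export
displacement_field <- function(ux, uy, spacing, units = c("px", "um"),
                               pixel_size = 0.161, correlation = NULL,
                               valid = NULL, origin = c(1, 1)) {
  units <- match.arg(units)
  stopifnot(is.matrix(ux), is.matrix(uy), all(dim(ux) == dim(uy)))
  if (!is.null(correlation)) {
    stopifnot(all(dim(correlation) == dim(ux)))
    if (any(correlation < -1e-9 | correlation > 1 + 1e-9, na.rm = TRUE)) {
      stop("correlation scores must lie in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(valid)) valid <- matrix(TRUE, nrow(ux), ncol(ux))
  structure(list(ux = ux, uy = uy, spacing = spacing, units = units,
                 pixel_size = pixel_size, correlation = correlation,
                 valid = valid, origin = origin),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2)
  cat(sprintf("<displacement_field> %dx%d, spacing %g px, |u| max %.3g %s, %d invalid\n",
              nrow(x$ux), ncol(x$ux), x$spacing, max(mag), x$units,
              sum(!x$valid)))
  invisible(x)
}

# Displacement components in um regardless of storage units.
displacement_um <- function(field) {
  f <- if (field$units == "px") field$pixel_size else 1
  list(ux = field$ux * f, uy = field$uy * f)
}

# Grid spacing in um.
field_spacing_um <- function(field) field$spacing * field$pixel_size

#' Traction field on a regular grid
#'
#' Traction stress vectors (Pa) on the displacement grid, with provenance.
#'
#' @param tx,ty Matrices of traction components, Pa.
#' @param spacing_um Grid spacing, um.
#' @param substrate The [elastic_substrate()] used for the inversion.
#' @param lambda Regularization weight actually applied.
#'
#' @return A `traction_field` with a precomputed `magnitude` matrix (Pa).
#' @export
traction_field <- function(tx, ty, spacing_um, substrate = NULL, lambda = NA) {
  stopifnot(is.matrix(tx), is.matrix(ty), all(dim(tx) == dim(ty)))
  if (!all(is.finite(tx)) || !all(is.finite(ty))) {
    stop("traction components must be finite everywhere", call. = FALSE)
  }
  structure(list(tx = tx, ty = ty, magnitude = sqrt(tx^2 + ty^2),
                 spacing_um = spacing_um, substrate = substrate,
                 lambda = lambda, mask = NULL),
            class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf("<traction_field> %dx%d, spacing %.3g um, |T| max %.4g Pa\n",
              nrow(x$tx), ncol(x$tx), x$spacing_um, max(x$magnitude)))
  invisible(x)
}
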