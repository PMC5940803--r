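# Spectral machinery shared by the forward (traction -> displacement) and
# inverse (FTTC) solutions of the elastic half-space (Boussinesq) problem.
#
# In Fourier space the surface displacement u and tangential traction T on a
# semi-infinite, homogeneous, isotropic substrate are linked by a 2x2 Green
# tensor per wavevector k = (kx, ky):
#
#   G(k) = 2 (1 + nu) / (E k^3) * [ (1-nu) k^2 + nu ky^2 ,  -nu kx ky
#                                   -nu kx ky            ,  (1-nu) k^2 + nu kx^2 ]
#
# with u_hat = G T_hat.  Units: E in Pa, k in rad/um, u in um, T in Pa.

# Angular wavenumbers for an n-point grid with spacing h (um).
fft_wavenumbers <- function(n, h) {
  m <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * m / (n * h)
}

# Green tensor component matrices on an (nr x nc) padded grid.
boussinesq_green <- function(nr, nc, h, E, nu) {
  ky <- fft_wavenumbers(nr, h)            # rows = y
  kx <- fft_wavenumbers(nc, h)            # cols = x
  KY <- matrix(ky, nr, nc)
  KX <- matrix(kx, nr, nc, byrow = TRUE)
  K2 <- KX^2 + KY^2
  K <- sqrt(K2)
  pref <- 2 * (1 + nu) / (E * K2 * K)
  pref[1, 1] <- 0                          # k = 0: indeterminate, zeroed
  gxx <- pref * ((1 - nu) * K2 + nu * KY^2)
  gyy <- pref * ((1 - nu) * K2 + nu * KX^2)
  gxy <- -pref * nu * KX * KY
  list(gxx = gxx, gxy = gxy, gyy = gyy)
}

# Zero-pad a matrix to (nr2 x nc2), keeping the data in the top-left block.
pad_to <- function(m, nr2, nc2) {
  out <- matrix(0, nr2, nc2)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# Cosine (Tukey) taper of the data region edges; alpha = tapered fraction.
cosine_taper <- function(n, alpha = 0.1) {
  w <- rep(1, n)
  edge <- max(1L, floor(alpha * n / 2))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(edge) - 0.5) / edge))
  w[seq_len(edge)] <- ramp
  w[n + 1 - seq_len(edge)] <- ramp
  w
}

#' Forward Boussinesq displacement from a traction field
#'
#' Computes the surface displacement of a semi-infinite elastic substrate
#' under a given tangential traction field, by multiplication with the
#' half-space Green tensor in Fourier space. Fields are zero-padded to twice
#' their linear size to suppress periodic wrap-around. This is the exact
#' forward model that [fttc()] inverts; an independent real-space summation
#' oracle is available as [forward_displacement_pointsum()].
#'
#' @param traction A [traction_field()] (Pa) on a regular grid.
#' @param substrate An [elastic_substrate()].
#' @param pad Zero-padding factor (>= 2); larger values push the periodic
#'   images further away at the cost of bigger FFTs, which matters when the
#'   far field must be accurate (slowly decaying dipole tails).
#'
#' @return A [displacement_field()] in um on the same grid, spacing carried
#'   over (spacing in px derived from the substrate pixel size).
#' @export
forward_displacement <- function(traction, substrate, pad = 2L) {
  stopifnot(inherits(traction, "traction_field"),
            inherits(substrate, "elastic_substrate"))
  nr <- nrow(traction$tx); nc <- ncol(traction$tx)
  h <- traction$spacing_um
  nr2 <- as.integer(pad) * nr; nc2 <- as.integer(pad) * nc
  G <- boussinesq_green(nr2, nc2, h, substrate$youngs_modulus, substrate$poisson)
  Tx <- stats::fft(pad_to(traction$tx, nr2, nc2))
  Ty <- stats::fft(pad_to(traction$ty, nr2, nc2))
  Ux <- G$gxx * Tx + G$gxy * Ty
  Uy <- G$gxy * Tx + G$gyy * Ty
  ux <- Re(stats::fft(Ux, inverse = TRUE)) / (nr2 * nc2)
  uy <- Re(stats::fft(Uy, inverse = TRUE)) / (nr2 * nc2)
  displacement_field(ux[seq_len(nr), seq_len(nc)], uy[seq_len(nr), seq_len(nc)],
                     spacing = h / substrate$pixel_size, units = "um",
                     pixel_size = substrate$pixel_size)
}

#' Real-space point-force displacement oracle
#'
#' Surface displacement obtained by summing the Boussinesq/Cerruti point-force
#' solution over every traction grid cell (treated as a point force
#' `T * h^2`). For a tangential point force F at the origin the surface
#' displacement at radius r is
#' \deqn{u_i = \frac{1+\nu}{\pi E r}\left[(1-\nu)\delta_{ij} +
#'   \nu \frac{r_i r_j}{r^2}\right] F_j .}
#' This is an O(N^2) reference implementation kept deliberately independent
#' of the spectral code path in [forward_displacement()]; it is accurate away
#' from the loaded cells (the point-force idealization diverges at r = 0,
#' where the singular self-term is skipped).
#'
#' @inheritParams forward_displacement
#' @return A [displacement_field()] in um on the traction grid.
#' @export
forward_displacement_pointsum <- function(traction, substrate) {
  stopifnot(inherits(traction, "traction_field"),
            inherits(substrate, "elastic_substrate"))
  h <- traction$spacing_um
  nr <- nrow(traction$tx); nc <- ncol(traction$tx)
  E <- substrate$youngs_modulus; nu <- substrate$poisson
  yy <- (seq_len(nr) - 1) * h
  xx <- (seq_len(nc) - 1) * h
  loaded <- which(traction$tx != 0 | traction$ty != 0, arr.ind = TRUE)
  ux <- matrix(0, nr, nc); uy <- matrix(0, nr, nc)
  X <- matrix(xx, nr, nc, byrow = TRUE)
  Y <- matrix(yy, nr, nc)
  for (i in seq_len(nrow(loaded))) {
    ry <- loaded[i, 1]; cx <- loaded[i, 2]
    fx <- traction$tx[ry, cx] * h^2
    fy <- traction$ty[ry, cx] * h^2
    dx <- X - xx[cx]; dy <- Y - yy[ry]
    r2 <- dx^2 + dy^2
    r <- sqrt(r2)
    inv_r <- ifelse(r > 0, 1 / r, 0)       # skip singular self-term
    pre <- (1 + nu) / (pi * E) * inv_r
    rr <- ifelse(r2 > 0, 1 / r2, 0)
    ux <- ux + pre * (((1 - nu) + nu * dx^2 * rr) * fx + nu * dx * dy * rr * fy)
    uy <- uy + pre * (nu * dx * dy * rr * fx + ((1 - nu) + nu * dy^2 * rr) * fy)
  }
  displacement_field(ux, uy, spacing = h / substrate$pixel_size, units = "um",
                     pixel_size = substrate$pixel_size)
}

# Shared core: returns the Fourier-domain quantities for a displacement field
# (padded), the Green tensor, and a solver for a given absolute regularizer.
fttc_core <- function(displacement, substrate, taper = 0.1) {
  u <- displacement_um(displacement)
  h <- field_spacing_um(displacement)
  nr <- nrow(u$ux); nc <- ncol(u$ux)
  if (nr < 2L || nc < 2L) stop("displacement grid too small", call. = FALSE)
  if (taper > 0) {
    w <- outer(cosine_taper(nr, taper), cosine_taper(nc, taper))
    u$ux <- u$ux * w
    u$uy <- u$uy * w
  }
  nr2 <- 2L * nr; nc2 <- 2L * nc
  G <- boussinesq_green(nr2, nc2, h, substrate$youngs_modulus, substrate$poisson)
  Ux <- stats::fft(pad_to(u$ux, nr2, nc2))
  Uy <- stats::fft(pad_to(u$uy, nr2, nc2))
  Ux[1, 1] <- 0; Uy[1, 1] <- 0
  # largest singular value of the symmetric tensor G over all k (for the
  # dimensionless lambda normalization)
  tr <- G$gxx + G$gyy
  disc <- sqrt((G$gxx - G$gyy)^2 + 4 * G$gxy^2)
  smax <- max((tr + disc) / 2)
  list(G = G, Ux = Ux, Uy = Uy, smax = smax, nr = nr, nc = nc,
       nr2 = nr2, nc2 = nc2, h = h)
}

# Solve the (regularized) normal equations per wavevector; alpha is the
# absolute Tikhonov weight added to G'G.
fttc_solve_fourier <- function(core, alpha) {
  G <- core$G
  a <- G$gxx; b <- G$gxy; d <- G$gyy
  Mxx <- a^2 + b^2 + alpha
  Mxy <- b * (a + d)
  Myy <- d^2 + b^2 + alpha
  det <- Mxx * Myy - Mxy^2
  det[det == 0] <- Inf
  r1 <- a * core$Ux + b * core$Uy
  r2 <- b * core$Ux + d * core$Uy
  Tx <- (Myy * r1 - Mxy * r2) / det
  Ty <- (Mxx * r2 - Mxy * r1) / det
  Tx[1, 1] <- 0; Ty[1, 1] <- 0
  list(Tx = Tx, Ty = Ty)
}

#' Fourier-transform traction cytometry (FTTC)
#'
#' Recovers the traction field exerted on an elastic substrate from the
#' measured bead displacement field by Tikhonov-regularized spectral inversion
#' of the Boussinesq problem. The regularized solution per wavevector is
#' \deqn{\hat T = (G^\top G + \alpha I)^{-1} G^\top \hat u}
#' with `alpha = lambda * smax^2`, where `smax` is the largest singular value
#' of the Green tensor over the sampled wavevectors. This makes `lambda`
#' dimensionless and portable across grid sizes and stiffnesses: `lambda = 0`
#' is the unregularized inverse; values around `1e-4`..`1e-2` are typical for
#' noisy data (select with [l_curve_sweep()]).
#'
#' Invalid vectors are interpolated from valid neighbours before inversion;
#' fields are edge-tapered and zero-padded to 2x linear size to control
#' periodic wrap-around.
#'
#' @param displacement A [displacement_field()] (complete regular grid).
#' @param substrate An [elastic_substrate()]; its `lambda` is used unless
#'   overridden.
#' @param lambda Optional override of the regularization weight.
#' @param taper Tapered edge fraction (0 disables).
#'
#' @return A [traction_field()] in Pa on the displacement grid.
#' @export
fttc <- function(displacement, substrate, lambda = NULL, taper = 0.1) {
  stopifnot(inherits(displacement, "displacement_field"),
            inherits(substrate, "elastic_substrate"))
  if (is.null(lambda)) lambda <- substrate$lambda
  check_scalar(lambda, "lambda", 0)
  displacement <- fill_invalid_vectors(displacement)
  core <- fttc_core(displacement, substrate, taper = taper)
  sol <- fttc_solve_fourier(core, alpha = lambda * core$smax^2)
  tx <- Re(stats::fft(sol$Tx, inverse = TRUE)) / (core$nr2 * core$nc2)
  ty <- Re(stats::fft(sol$Ty, inverse = TRUE)) / (core$nr2 * core$nc2)
  traction_field(tx[seq_len(core$nr), seq_len(core$nc)],
                 ty[seq_len(core$nr), seq_len(core$nc)],
                 spacing_um = core$h, substrate = substrate, lambda = lambda)
}

# Replace invalid vectors by the median of valid 8-neighbours, then by
# iterative dilation for isolated holes.
fill_invalid_vectors <- function(field) {
  if (all(field$valid)) return(field)
  ux <- field$ux; uy <- field$uy; valid <- field$valid
  for (pass in 1:100) {
    bad <- which(!valid, arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    progressed <- FALSE
    for (i in seq_len(nrow(bad))) {
      r <- bad[i, 1]; c <- bad[i, 2]
      rr <- max(1, r - 1):min(nrow(ux), r + 1)
      cc <- max(1, c - 1):min(ncol(ux), c + 1)
      nb <- valid[rr, cc]
      if (any(nb)) {
        ux[r, c] <- stats::median(ux[rr, cc][nb])
        uy[r, c] <- stats::median(uy[rr, cc][nb])
        valid[r, c] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (any(!valid)) {
    ux[!valid] <- 0; uy[!valid] <- 0
    valid[] <- TRUE
  }
  field$ux <- ux; field$uy <- uy; field$valid <- valid
  field
}

#' L-curve sweep for regularization selection
#'
#' Computes residual norm `||G T_lambda - u||` and solution norm
#' `||T_lambda||` across a sequence of regularization weights and selects the
#' weight at the point of maximum curvature of the log-log L-curve (the
#' "corner"). The curvature maximum is found by central finite differences on
#' the sampled curve, so the answer is resolved to one grid step of the
#' supplied `lambdas`.
#'
#' @param displacement A [displacement_field()].
#' @param substrate An [elastic_substrate()].
#' @param lambdas Increasing positive sequence (>= 5 values spanning several
#'   decades recommended).
#' @param taper Edge taper fraction, as in [fttc()].
#'
#' @return List: `lambda` (chosen weight), `index`, `table` (data.frame with
#'   `lambda`, `residual_norm`, `solution_norm`, `curvature`), and `flag`
#'   (`"ok"`, `"boundary"` if the corner sits at the end of the sweep, or
#'   `"no-corner"` for a degenerate curve).
#' @export
l_curve_sweep <- function(displacement, substrate, lambdas, taper = 0.1) {
  stopifnot(length(lambdas) >= 5L, all(lambdas > 0), !is.unsorted(lambdas))
  displacement <- fill_invalid_vectors(displacement)
  core <- fttc_core(displacement, substrate, taper = taper)
  npix <- core$nr2 * core$nc2
  res <- sol <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    s <- fttc_solve_fourier(core, alpha = lambdas[i] * core$smax^2)
    # Parseval: norms evaluated in the Fourier domain
    Rx <- core$G$gxx * s$Tx + core$G$gxy * s$Ty - core$Ux
    Ry <- core$G$gxy * s$Tx + core$G$gyy * s$Ty - core$Uy
    res[i] <- sqrt((sum(Mod(Rx)^2) + sum(Mod(Ry)^2)) / npix)
    sol[i] <- sqrt((sum(Mod(s$Tx)^2) + sum(Mod(s$Ty)^2)) / npix)
  }
  corner <- l_curve_corner(lambdas, res, sol)
  list(lambda = lambdas[corner$index], index = corner$index,
       table = data.frame(lambda = lambdas, residual_norm = res,
                          solution_norm = sol, curvature = corner$curvature),
       flag = corner$flag)
}

#' L-curve corner from precomputed norms
#'
#' Generic corner finder used by [l_curve_sweep()] and applicable to any
#' Tikhonov problem: given regularization weights and the associated residual
#' and solution norms, returns the index of maximum curvature of the
#' parametric curve `(log residual, log solution)` with respect to
#' `log(lambda)`, by central finite differences.
#'
#' @param lambdas Increasing positive weights.
#' @param residual_norms,solution_norms Positive norm sequences.
#'
#' @return List: `index`, `curvature` (vector, `NA` at the ends), `flag`.
#' @export
l_curve_corner <- function(lambdas, residual_norms, solution_norms) {
  n <- length(lambdas)
  stopifnot(n >= 3L, length(residual_norms) == n, length(solution_norms) == n)
  t <- log(lambdas)
  x <- log(pmax(residual_norms, .Machine$double.xmin))
  y <- log(pmax(solution_norms, .Machine$double.xmin))
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    h1 <- t[i] - t[i - 1]; h2 <- t[i + 1] - t[i]
    xp <- (x[i + 1] - x[i - 1]) / (h1 + h2)
    yp <- (y[i + 1] - y[i - 1]) / (h1 + h2)
    xpp <- 2 * (h1 * x[i + 1] - (h1 + h2) * x[i] + h2 * x[i - 1]) /
      (h1 * h2 * (h1 + h2))
    ypp <- 2 * (h1 * y[i + 1] - (h1 + h2) * y[i] + h2 * y[i - 1]) /
      (h1 * h2 * (h1 + h2))
    denom <- (xp^2 + yp^2)^1.5
    # sign such that the bend of the L (solution norm falling away as the
    # residual grows) is a positive maximum
    kappa[i] <- if (denom > 0) (yp * xpp - xp * ypp) / denom else NA_real_
  }
  finite <- which(is.finite(kappa))
  if (length(finite) == 0L || max(kappa[finite]) <= 0) {
    return(list(index = 1L, curvature = kappa, flag = "no-corner"))
  }
  idx <- finite[which.max(kappa[finite])]
  flag <- if (idx <= 2L || idx >= n - 1L) "boundary" else "ok"
  list(index = idx, curvature = kappa, flag = flag)
}

#' Clear traction outside a cell contour
#'
#' Zeroes traction vectors outside a closed polygon (the manually outlined
#' cell contour), so that the metrics reflect only forces under the cell.
#' The polygon is given in image pixel coordinates (x rightward, y downward,
#' pixel-centred) or directly in traction-grid coordinates.
#'
#' @param traction A [traction_field()].
#' @param contour Two-column matrix of polygon vertices `(x, y)`, or a
#'   logical mask matrix matching the traction grid.
#' @param coords `"image"` (px; converted using the field spacing and the
#'   grid `origin`) or `"grid"` (traction grid indices).
#' @param origin Image coordinates (row, col) of grid point `[1, 1]` when
#'   `coords = "image"`.
#'
#' @return The traction field with a `mask` attached and outside values
#'   zeroed.
#' @export
mask_traction <- function(traction, contour, coords = c("grid", "image"),
                          origin = c(1, 1)) {
  stopifnot(inherits(traction, "traction_field"))
  coords <- match.arg(coords)
  nr <- nrow(traction$tx); nc <- ncol(traction$tx)
  if (is.matrix(contour) && (is.logical(contour) ||
                             all(contour %in% c(0, 1))) &&
      all(dim(contour) == c(nr, nc))) {
    mask <- matrix(as.logical(contour), nr, nc)
  } else {
    contour <- as.matrix(contour)
    if (ncol(contour) != 2L || nrow(contour) < 3L) {
      stop("`contour` must be a closed polygon with >= 3 vertices", call. = FALSE)
    }
    px <- contour[, 1]; py <- contour[, 2]
    if (coords == "image") {
      sp <- traction$spacing_um / traction$substrate$pixel_size
      px <- (px - origin[2]) / sp + 1
      py <- (py - origin[1]) / sp + 1
    }
    gx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    gy <- matrix(seq_len(nr), nr, nc)
    inp <- pracma::inpolygon(as.vector(gx), as.vector(gy), px, py,
                             boundary = TRUE)
    mask <- matrix(inp, nr, nc)
  }
  if (!any(mask)) stop("contour encloses no traction grid points", call. = FALSE)
  traction$tx[!mask] <- 0
  traction$ty[!mask] <- 0
  traction$magnitude[!mask] <- 0
  traction$mask <- mask
  traction
}

#' Traction metrics over the cell mask
#'
#' Maximum and mean traction magnitude over the masked region, the cell area,
#' and total cell strength defined as the product of the cell area (um^2) and
#' the mean traction, reported in Pa um^2 (divide by 1000 for kPa um^2).
#'
#' @param traction A [traction_field()], usually after [mask_traction()]; if
#'   unmasked, the whole grid is used.
#'
#' @return List: `max_traction` (Pa), `mean_traction` (Pa), `cell_area`
#'   (um^2), `total_strength` (Pa um^2), `n_grid_points`.
#' @export
traction_metrics <- function(traction) {
  stopifnot(inherits(traction, "traction_field"))
  mask <- traction$mask
  if (is.null(mask)) mask <- matrix(TRUE, nrow(traction$tx), ncol(traction$tx))
  if (!any(mask)) stop("empty traction mask", call. = FALSE)
  mag <- traction$magnitude[mask]
  area <- sum(mask) * traction$spacing_um^2
  mean_t <- mean(mag)
  list(max_traction = max(mag), mean_traction = mean_t, cell_area = area,
       total_strength = area * mean_t, n_grid_points = sum(mask))
}
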