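#' Simulation configuration
#'
#' Bundles the random seed and noise level shared by every synthetic-data
#' generator. Identical configurations (including the seed) produce
#' bit-identical output; `noise_sd = 0` reduces each generator to its
#' noiseless analytic skeleton.
#'
#' @param seed Integer random seed.
#' @param noise_sd Non-negative noise standard deviation, in the units of the
#'   signal each generator perturbs (see the individual generators).
#' @param ... Further generator-specific geometry parameters, stored as-is.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, noise_sd = 0, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), noise_sd = noise_sd, ...),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed =", x$seed, " noise_sd =", x$noise_sd, "\n")
  invisible(x)
}

# Evaluate `expr` under a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards.  All generator randomness flows through
# this helper so that no global state leaks between calls.
with_seed <- function(seed, expr) {
  env <- globalenv()
  has_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

# Bilinear interpolation of matrix `m` at (row, col) positions given in
# pixel-centred 1-based coordinates.  Out-of-range positions clamp to edges.
bilinear_at <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(row, 1), nr)
  c <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# Shift an image by (dr, dc) pixels (possibly fractional) using bilinear
# interpolation; uncovered borders are zero-filled.  Positive dr moves
# content down, positive dc moves it right.
shift_image <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc) - dr
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dc
  out <- matrix(0, nr, nc)
  inside <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  out[inside] <- bilinear_at(img, rows[inside], cols[inside])
  out
}

# Render Gaussian spots (sigma px) of given peak intensities at subpixel
# positions (row, col; 1-based) onto an nr x nc canvas.
render_spots <- function(nr, nc, row, col, sigma = 1.5, intensity = 1) {
  img <- matrix(0, nr, nc)
  if (length(row) == 0L) return(img)
  intensity <- rep_len(intensity, length(row))
  half <- ceiling(4 * sigma)
  for (i in seq_along(row)) {
    r0 <- max(1L, floor(row[i]) - half); r1 <- min(nr, ceiling(row[i]) + half)
    c0 <- max(1L, floor(col[i]) - half); c1 <- min(nc, ceiling(col[i]) + half)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    g <- outer(exp(-(rr - row[i])^2 / (2 * sigma^2)),
               exp(-(cc - col[i])^2 / (2 * sigma^2)))
    img[rr, cc] <- img[rr, cc] + intensity[i] * g
  }
  img
}

# Otsu threshold from a 256-bin histogram of a numeric matrix.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite pixels for thresholding", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(pmax(floor((x - lo) / (hi - lo) * 256) + 1L, 1L), 256L),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + (k / 256) * (hi - lo)
}

largest_component <- function(labels) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which.max(sizes)
  matrix(as.integer(labels == keep), nrow(labels), ncol(labels))
}
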