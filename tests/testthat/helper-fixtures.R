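# Shared fixture builders.  All fixtures are generated in code; no files.

# Bright disk on a dark background.
disk_image <- function(size = 512L, r = 100, centre = (size + 1) / 2,
                       bg = 0.2, fg = 0.7) {
  X <- matrix(seq_len(size), size, size, byrow = TRUE)
  Y <- matrix(seq_len(size), size, size)
  img <- matrix(bg, size, size)
  img[(X - centre)^2 + (Y - centre)^2 <= r^2] <- fg
  img
}

# Random bead field and its subpixel-translated copy.
bead_pair <- function(n = 1500L, size = 384L, shift = c(0, 0), seed = 7L) {
  set.seed(seed)
  pos <- cbind(runif(n, 1, size), runif(n, 1, size))
  list(reference = render_bead_image(pos, c(size, size)),
       deformed = render_bead_image(cbind(pos[, 1] + shift[1],
                                          pos[, 2] + shift[2]),
                                    c(size, size)),
       positions = pos)
}

# Field of solid ellipses (axis ratio `aspect`) on a placement grid, for
# focal-adhesion fixtures; returns the image and the true count.
ellipse_field <- function(n = 20L, size = 320L, a = 9, aspect = 3,
                          bg = 0.05, fg = 0.8, seed = 8L) {
  set.seed(seed)
  b <- a / aspect
  pitch <- ceiling(2.6 * a)
  per_row <- floor((size - pitch) / pitch)
  stopifnot(n <= per_row^2)
  sites <- sample(per_row^2, n)
  img <- matrix(bg, size, size)
  X0 <- matrix(seq_len(size), size, size, byrow = TRUE)
  Y0 <- matrix(seq_len(size), size, size)
  for (s in sites) {
    cx <- ((s - 1) %% per_row) * pitch + pitch
    cy <- ((s - 1) %/% per_row) * pitch + pitch
    ang <- runif(1, 0, pi)
    X <- X0 - cx; Y <- Y0 - cy
    Xr <- X * cos(ang) + Y * sin(ang)
    Yr <- -X * sin(ang) + Y * cos(ang)
    img[(Xr / a)^2 + (Yr / b)^2 <= 1] <- fg
  }
  img
}

# Small classical ill-posed Tikhonov problem (discretized Gaussian blur of a
# smooth signal plus noise), with norms computed from the SVD.  Used to
# exercise L-curve corner selection against a brute-force oracle.
tikhonov_toy <- function(n = 64L, noise = 1e-3, seed = 1L) {
  set.seed(seed)
  x <- seq(0, 1, length.out = n)
  A <- outer(x, x, function(s, t) exp(-(s - t)^2 / (2 * 0.03^2)))
  A <- A / sum(A[1, ])
  xtrue <- sin(2 * pi * x) + 0.5 * sin(6 * pi * x)
  b <- A %*% xtrue + rnorm(n, 0, noise)
  sv <- svd(A)
  beta <- drop(crossprod(sv$u, b))
  norms <- function(alpha) {
    f <- sv$d^2 / (sv$d^2 + alpha)
    eta <- sqrt(sum((f * beta / sv$d)^2))
    rho <- sqrt(sum(((1 - f) * beta)^2))
    c(rho, eta)
  }
  list(A = A, b = b, xtrue = xtrue, norms = norms)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
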