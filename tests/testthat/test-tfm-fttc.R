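# Forward Boussinesq model, FTTC inversion, L-curve, masking, metrics.

make_sub <- function(E = 25000, lambda = 0) {
  elastic_substrate(E, poisson = 0.5, pixel_size = 0.161, lambda = lambda)
}

test_that("forward displacement is linear and vanishes for zero traction", {
  zero <- traction_field(matrix(0, 64, 64), matrix(0, 64, 64), spacing_um = 0.5)
  d0 <- forward_displacement(zero, make_sub())
  expect_true(all(d0$ux == 0) && all(d0$uy == 0))
  tr <- traction_dipole(image_size = c(64L, 64L), pixel_size = 0.5,
                        peak = 800, patch_sigma = 2, separation = 10)
  sub <- make_sub()
  d1 <- forward_displacement(tr, sub)
  tr2 <- traction_field(2 * tr$tx, 2 * tr$ty, tr$spacing_um)
  expect_equal(forward_displacement(tr2, sub)$ux, 2 * d1$ux, tolerance = 1e-12)
  dE <- forward_displacement(tr, make_sub(E = 50000))
  expect_equal(dE$ux, d1$ux / 2, tolerance = 1e-12)
})

test_that("spectral forward model agrees with the real-space point-force oracle", {
  tr <- traction_dipole(image_size = c(128L, 128L), pixel_size = 0.5,
                        peak = 1000, patch_sigma = 3, separation = 20)
  sub <- make_sub()
  spec <- forward_displacement(tr, sub, pad = 6)
  oracle <- forward_displacement_pointsum(tr, sub)
  m_spec <- sqrt(spec$ux^2 + spec$uy^2)
  m_orc <- sqrt(oracle$ux^2 + oracle$uy^2)
  # compare away from the loaded patches, where the point-force
  # idealization is valid and the signal is well above padding residue
  valid <- tr$magnitude < 0.01 * max(tr$magnitude) & m_orc > 0.1 * max(m_orc)
  expect_gt(sum(valid), 500)
  rel <- abs(m_spec[valid] - m_orc[valid]) / m_orc[valid]
  expect_lt(median(rel), 0.01)
  # direction at the patch centre aligns with the applied traction (+x)
  centre <- which(tr$tx == max(tr$tx), arr.ind = TRUE)[1, ]
  expect_gt(spec$ux[centre[1], centre[2]], 0)
  expect_lt(abs(spec$uy[centre[1], centre[2]]),
            0.05 * abs(spec$ux[centre[1], centre[2]]))
})

test_that("FTTC inverts the forward model on noiseless band-limited fields", {
  tr <- traction_dipole(image_size = c(128L, 128L), pixel_size = 0.5,
                        peak = 1000, patch_sigma = 3, separation = 20)
  sub <- make_sub()
  d <- forward_displacement(tr, sub)
  rec <- fttc(d, sub, lambda = 1e-8)
  expect_gt(cor(as.vector(rec$magnitude), as.vector(tr$magnitude)), 0.95)
  expect_rel_equal(max(rec$magnitude), max(tr$magnitude), 0.2)
  # zero displacement -> zero traction
  z <- displacement_field(matrix(0, 32, 32), matrix(0, 32, 32), spacing = 8,
                          units = "um")
  tz <- fttc(z, sub, lambda = 0)
  expect_true(all(tz$magnitude == 0))
})

test_that("traction scales exactly with the modulus used for inversion", {
  tr <- traction_dipole(image_size = c(64L, 64L), pixel_size = 0.5,
                        peak = 500, patch_sigma = 2, separation = 10)
  d <- forward_displacement(tr, make_sub(E = 25000))
  t3 <- fttc(d, make_sub(E = 3000), lambda = 0, taper = 0)
  t25 <- fttc(d, make_sub(E = 25000), lambda = 0, taper = 0)
  t125 <- fttc(d, make_sub(E = 125000), lambda = 0, taper = 0)
  expect_equal(t25$tx, t3$tx * 25 / 3, tolerance = 1e-12)
  expect_equal(t125$tx, t3$tx * 125 / 3, tolerance = 1e-12)
  expect_equal(t125$ty, t25$ty * 5, tolerance = 1e-12)
})

test_that("invalid vectors are filled from valid neighbours before inversion", {
  tr <- traction_dipole(image_size = c(64L, 64L), pixel_size = 0.5,
                        peak = 500, patch_sigma = 2, separation = 10)
  d <- forward_displacement(tr, make_sub())
  valid <- matrix(TRUE, 64, 64); valid[30, 30] <- FALSE
  dd <- displacement_field(d$ux, d$uy, spacing = d$spacing, units = "um",
                           pixel_size = d$pixel_size, valid = valid)
  dd$ux[30, 30] <- 99  # corrupted vector must be ignored
  filled <- mechanoquant:::fill_invalid_vectors(dd)
  expect_true(filled$valid[30, 30])
  expect_lt(abs(filled$ux[30, 30]), 1)
})

test_that("L-curve norms are monotone in lambda", {
  tr <- traction_dipole(image_size = c(64L, 64L), pixel_size = 0.5,
                        peak = 500, patch_sigma = 2, separation = 10)
  d <- forward_displacement(tr, make_sub())
  d$ux <- d$ux + 0.002 * matrix(rnorm(64 * 64), 64, 64)
  sw <- l_curve_sweep(d, make_sub(), 10^seq(-6, 0, by = 0.5))
  expect_true(all(diff(sw$table$solution_norm) <= 1e-9))
  expect_true(all(diff(sw$table$residual_norm) >= -1e-12))
})

test_that("L-curve corner matches a brute-force curvature search on a toy problem", {
  toy <- tikhonov_toy(n = 64, noise = 1e-3, seed = 1)
  # package route: coarse sweep
  coarse <- 10^seq(-10, 0, by = 0.25)
  nm <- t(vapply(coarse, toy$norms, numeric(2)))
  sel <- l_curve_corner(coarse, nm[, 1], nm[, 2])
  # brute-force oracle: dense grid, curvature from raw finite differences of
  # the log-log curve computed locally (independent code path)
  dense <- 10^seq(-10, 0, length.out = 2000)
  nd <- t(vapply(dense, toy$norms, numeric(2)))
  x <- log(nd[, 1]); y <- log(nd[, 2]); t <- log(dense)
  xp <- diff(x) / diff(t); yp <- diff(y) / diff(t)
  xpp <- diff(xp) / diff(t[-1]); ypp <- diff(yp) / diff(t[-1])
  xpm <- (xp[-1] + xp[-length(xp)]) / 2
  ypm <- (yp[-1] + yp[-length(yp)]) / 2
  kappa <- (ypm * xpp - xpm * ypp) / (xpm^2 + ypm^2)^1.5
  lam_oracle <- dense[which.max(kappa) + 1L]
  # agreement within one coarse grid step (quarter decade)
  expect_lt(abs(log10(coarse[sel$index]) - log10(lam_oracle)), 0.25 + 1e-9)
})

test_that("degenerate noiseless systems flag a boundary or missing corner", {
  toy <- tikhonov_toy(n = 48, noise = 0, seed = 2)
  lams <- 10^seq(-12, -2, by = 0.5)
  nm <- t(vapply(lams, toy$norms, numeric(2)))
  sel <- l_curve_corner(lams, nm[, 1], nm[, 2])
  expect_true(sel$flag %in% c("boundary", "no-corner"))
})

test_that("masking clears outside the contour and preserves the inside", {
  tx <- matrix(100, 20, 20)
  tf <- traction_field(tx, tx * 0, spacing_um = 1)
  full <- mask_traction(tf, cbind(c(0.5, 20.5, 20.5, 0.5),
                                  c(0.5, 0.5, 20.5, 20.5)))
  expect_equal(full$tx, tx)
  half <- mask_traction(tf, cbind(c(0.5, 10.4, 10.4, 0.5),
                                  c(0.5, 0.5, 20.5, 20.5)))
  expect_equal(sum(half$mask), 200L)
  expect_equal(mean(half$magnitude[half$mask]), 100)
  expect_error(mask_traction(tf, cbind(c(100, 110, 110), c(100, 100, 110))),
               "no traction grid points")
})

test_that("traction metrics satisfy their identities to machine precision", {
  # uniform 100 Pa over 1000 um^2: 10x10 grid with sqrt(10) um spacing
  tf <- traction_field(matrix(100, 10, 10), matrix(0, 10, 10),
                       spacing_um = sqrt(10))
  m <- traction_metrics(tf)
  expect_equal(m$max_traction, 100)
  expect_equal(m$mean_traction, 100)
  expect_equal(m$cell_area, 1000)
  expect_identical(m$total_strength, m$cell_area * m$mean_traction)
  # single nonzero cell
  tx <- matrix(0, 8, 8); tx[3, 5] <- 250
  m1 <- traction_metrics(traction_field(tx, tx * 0, spacing_um = 2))
  expect_equal(m1$max_traction, 250)
  expect_equal(m1$mean_traction, 250 / 64)
  # brute-force loop agreement on a random masked field
  set.seed(5)
  tx <- matrix(rnorm(144), 12, 12); ty <- matrix(rnorm(144), 12, 12)
  tf2 <- traction_field(tx, ty, spacing_um = 1.5)
  mask <- matrix(runif(144) > 0.4, 12, 12)
  masked <- mask_traction(tf2, mask)
  m2 <- traction_metrics(masked)
  acc <- 0; mx <- -Inf; n <- 0
  for (i in 1:12) for (j in 1:12) if (mask[i, j]) {
    v <- sqrt(tx[i, j]^2 + ty[i, j]^2)
    acc <- acc + v; mx <- max(mx, v); n <- n + 1
  }
  expect_equal(m2$mean_traction, acc / n)
  expect_equal(m2$max_traction, mx)
  expect_equal(m2$cell_area, n * 1.5^2)
})
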