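# Cell areas, focal-adhesion morphometry, colocalization, linescans,
# nuclear:cytoplasmic ratios.

test_that("cell area recovers a known footprint within 2 percent", {
  # ~1673 um^2 footprint at 0.1075 um/px -> disk of radius ~214.6 px
  r <- sqrt(1673 / pi) / 0.1075
  img <- disk_image(size = 512, r = r, bg = 0.05, fg = 0.6)
  cm <- cell_area(img, pixel_size = 0.1075)
  expect_rel_equal(cm$area, 1673, 0.02)
  expect_false(cm$multiple_cells)
  expect_error(cell_area(matrix(0, 64, 64)), "empty")
})

test_that("a second sizeable cell raises the multiple-cell flag", {
  img <- disk_image(size = 400, r = 60, bg = 0.05, fg = 0.6)
  X <- matrix(1:400, 400, 400, byrow = TRUE); Y <- t(X)
  img[(X - 320)^2 + (Y - 310)^2 <= 40^2] <- 0.6
  cm <- cell_area(img, pixel_size = 0.1075)
  expect_true(cm$multiple_cells)
  expect_rel_equal(cm$area, pi * 60^2 * 0.1075^2, 0.02)
})

test_that("focal adhesions are counted and measured", {
  img <- ellipse_field(n = 20, a = 9, aspect = 3)
  rois <- segment_adhesions(img, pixel_size = 0.1075)
  expect_equal(nrow(rois), 20L)
  expect_lt(abs(mean(rois$aspect_ratio) - 3) / 3, 0.05)
  expect_equal(nrow(segment_adhesions(matrix(0.05, 128, 128))), 0L)
  # circular blob -> aspect ratio ~ 1
  blob <- disk_image(size = 128, r = 10, bg = 0.05, fg = 0.8)
  rb <- segment_adhesions(blob, pixel_size = 0.1075)
  expect_equal(nrow(rb), 1L)
  expect_lt(abs(rb$aspect_ratio - 1), 0.05)
})

test_that("adhesion intensity ratios equal brute-force per-pixel averaging", {
  img <- ellipse_field(n = 12, a = 8, aspect = 2.5, seed = 61)
  rois <- segment_adhesions(img, pixel_size = 0.1075)
  same <- adhesion_intensity_ratio(rois, img, img)
  expect_true(all(same$ratios$ratio == 1))
  doubled <- adhesion_intensity_ratio(rois, 2 * img, img)
  expect_true(all(doubled$ratios$ratio == 2))
  set.seed(62)
  num <- matrix(runif(length(img), 0.1, 1), nrow(img), ncol(img))
  den <- matrix(runif(length(img), 0.1, 1), nrow(img), ncol(img))
  air <- adhesion_intensity_ratio(rois, num, den)
  pix <- attr(rois, "pixels")
  for (k in seq_along(pix)) {
    expect_equal(air$ratios$ratio[k], mean(num[pix[[k]]]) / mean(den[pix[[k]]]))
  }
  # zero denominator -> flagged and excluded
  zden <- den; zden[pix[[1]]] <- 0
  az <- adhesion_intensity_ratio(rois, num, zden)
  expect_true(az$ratios$excluded[1])
  expect_true(is.na(az$ratios$ratio[1]))
})

test_that("Manders coefficients hit the degenerate limits and are scale invariant", {
  g <- gen_coloc_images(overlap = 1, cfg = sim_config(63))
  m <- manders(g$channel_a, g$channel_b)
  expect_equal(m$manders_m1, 1)
  expect_equal(m$manders_m2, 1)
  g0 <- gen_coloc_images(overlap = 0, cfg = sim_config(63))
  m0 <- manders(g0$channel_a, g0$channel_b)
  expect_equal(m0$manders_m1, 0)
  expect_equal(m0$manders_m2, 0)
  gh <- gen_coloc_images(overlap = 0.5, cfg = sim_config(64))
  mh <- manders(gh$channel_a, gh$channel_b)
  expect_lt(abs(mh$manders_m1 - gh$truth$m1), 0.05)
  expect_lt(abs(mh$manders_m2 - gh$truth$m2), 0.05)
  # multiplying a channel by a positive constant leaves M unchanged
  ms <- manders(3.7 * gh$channel_a, gh$channel_b)
  expect_equal(ms$manders_m1, mh$manders_m1)
  expect_equal(ms$manders_m2, mh$manders_m2)
  expect_error(manders(matrix(0, 8, 8), matrix(1, 8, 8)), "all zero")
})

test_that("Manders truth matches a brute-force sum over the true supports", {
  g <- gen_coloc_images(overlap = 0.5, cfg = sim_config(65))
  m1_bf <- sum(g$channel_a[g$truth$support_b]) / sum(g$channel_a)
  expect_equal(manders(g$channel_a, g$channel_b)$manders_m1, m1_bf)
})

test_that("linescan Pearson correlations follow the constructed geometry", {
  set.seed(66)
  img <- matrix(runif(128 * 128), 128, 128)
  prof <- linescan(img, c(10, 20), c(110, 100), width = 3)
  expect_equal(pearson_linescan(prof, prof), 1)
  expect_equal(pearson_linescan(prof, -prof), -1)
  # affine transforms of a profile leave r unchanged
  expect_equal(pearson_linescan(prof, 4 * prof + 2), 1)
  s <- seq(0, 6 * pi, length.out = 200)
  expect_lt(abs(pearson_linescan(sin(s), cos(s))), 0.05)
  expect_error(linescan(img, c(10, 10), c(10, 10)), "degenerate")
})

test_that("linescan sampling matches a horizontal image row", {
  img <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64, 64)
  prof <- linescan(img, c(1, 32), c(64, 32), n = 64)
  expect_equal(prof, seq(0, 1, length.out = 64), tolerance = 1e-9)
})

test_that("nuclear:cytoplasmic ratio is exact on constructions and scale invariant", {
  g <- gen_nc_cell(ratio = 2, cfg = sim_config(67))
  r <- nuc_cyto_ratio(g$signal, g$nuclear_mask, g$cell_mask)
  expect_equal(r$ratio, 2)
  # uniform image -> ratio 1
  u <- nuc_cyto_ratio(matrix(0.5, 128, 128), g$nuclear_mask, g$cell_mask)
  expect_equal(u$ratio, 1)
  # global intensity scaling cancels
  r2 <- nuc_cyto_ratio(5 * g$signal, g$nuclear_mask, g$cell_mask)
  expect_equal(r2$ratio, 2)
  # strictly increasing in nuclear signal
  boosted <- g$signal
  boosted[g$nuclear_mask] <- boosted[g$nuclear_mask] * 1.3
  expect_gt(nuc_cyto_ratio(boosted, g$nuclear_mask, g$cell_mask)$ratio, 2)
  expect_error(nuc_cyto_ratio(g$signal, g$cell_mask, g$nuclear_mask), "inside")
})

test_that("noisy N:C recovery is unbiased within 3 percent over seeds", {
  vals <- vapply(1:50, function(s) {
    g <- gen_nc_cell(ratio = 2, cfg = sim_config(s, noise_sd = 0.05))
    nuc_cyto_ratio(g$signal, g$nuclear_mask, g$cell_mask)$ratio
  }, 0)
  expect_lt(abs(mean(vals) - 2) / 2, 0.03)
})
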