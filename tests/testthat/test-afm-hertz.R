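# Hertz force law, contact detection, curve fitting, force maps, summaries.

test_that("hertz_force obeys the closed form and its homogeneity", {
  expect_equal(hertz_force(4330, 0), 0)
  d <- c(0.2, 0.7, 1.3)
  expect_equal(hertz_force(2 * 4330, d), 2 * hertz_force(4330, d))
  expect_equal(hertz_force(4330, 4 * d), 8 * hertz_force(4330, d))
  # independently hand-computed value: E = 25.56 kPa, R = 2.5 um, nu = 0.5,
  # delta = 1 um -> 71.84695 nN
  expect_equal(hertz_force(25560, 1, 2.5, 0.5), 71.84695, tolerance = 1e-6)
  expect_error(hertz_force(4330, -0.1), "indentation")
  expect_error(hertz_force(-1, 0.5), "E")
})

test_that("contact point is recovered from synthetic curves", {
  g <- gen_force_curve(E = 4330, contact_offset = 0.5, cfg = sim_config(1))
  spacing <- diff(g$curve$z[1:2])
  cd <- detect_contact_point(g$curve)
  expect_lt(abs(cd$contact_point - 0.5), spacing)
  # contact at the very first sample
  g0 <- gen_force_curve(E = 4330, contact_offset = 0, cfg = sim_config(2))
  cd0 <- detect_contact_point(g0$curve)
  expect_lt(abs(cd0$contact_point), 0.05)
  flat <- force_curve(z = seq(0, 2, length.out = 100),
                      force = rep(0, 100))
  expect_error(detect_contact_point(flat), "flat")
})

test_that("noiseless Hertz fits recover the modulus across the working range", {
  for (E in c(1e3, 4.33e3, 25.56e3, 80e3, 200e3)) {
    g <- gen_force_curve(E = E, cfg = sim_config(3))
    fit <- fit_hertz(g$curve)
    expect_true(fit$converged)
    expect_rel_equal(fit$E, E, 0.005)
  }
})

test_that("fit window choice does not matter for noiseless data", {
  g <- gen_force_curve(E = 4330, cfg = sim_config(4))
  e1 <- fit_hertz(g$curve, window = c(0.15, 0.80))$E
  e2 <- fit_hertz(g$curve, window = c(0.01, 1.00))$E
  expect_rel_equal(e1, e2, 1e-4)
})

test_that("fit is invariant to baseline force and piezo-origin shifts", {
  g <- gen_force_curve(E = 25560, cfg = sim_config(5))
  base <- fit_hertz(g$curve)$E
  shifted <- force_curve(z = g$curve$z + 0.3, force = g$curve$force + 2.5,
                         probe_radius = 2.5, poisson = 0.5)
  expect_rel_equal(fit_hertz(shifted)$E, base, 1e-3)
})

test_that("modulus recovery under 2 percent force noise is accurate and unbiased", {
  fits <- vapply(1:100, function(s) {
    g <- gen_force_curve(E = 3000, cfg = sim_config(s, noise_sd = 0.02))
    fit_hertz(g$curve)$E
  }, 0)
  expect_lt(median(abs(fits - 3000) / 3000), 0.05)
  expect_lt(abs(mean(fits) - 3000) / 3000, 0.01)   # Monte-Carlo bias
})

test_that("force maps assemble, flag failures, and match hotspot truth", {
  curves <- lapply(1:64, function(i)
    gen_force_curve(E = 3060, cfg = sim_config(i))$curve)
  fm <- build_force_map(curves)
  expect_equal(dim(fm$E), c(8L, 8L))
  expect_true(all(abs(fm$E - 3060) / 3060 < 0.005))
  expect_equal(fm$spacing, 2.5)
  # a flat curve must be flagged, not zeroed
  curves[[10]] <- force_curve(z = seq(0, 2, length.out = 100),
                              force = rep(0, 100))
  fm2 <- build_force_map(curves)
  expect_equal(sum(is.na(fm2$E)), 1L)
  expect_error(build_force_map(curves[1:10]), "expected 64")
  # hotspot fixture: fitted grid matches the generator truth cellwise
  maps <- gen_force_map_grid(base_E = 4330, hotspot_fraction = 1,
                             n_maps = 1L, cfg = sim_config(77))
  fitted <- build_force_map(maps[[1]]$curves)
  expect_true(all(abs(fitted$E - maps[[1]]$truth$E_grid) /
                    maps[[1]]$truth$E_grid < 0.05))
})

test_that("heat maps respect local and global scaling", {
  mk <- function(E) structure(list(E = E, region_size = 20, spacing = 2.5,
                                   fits = list()), class = "force_map")
  m1 <- mk(matrix(seq(1000, 2000, length.out = 64), 8, 8))
  m2 <- mk(m1$E * 10)
  uni <- render_heatmap(mk(matrix(5000, 8, 8)), scaling = "local")[[1]]
  expect_equal(length(unique(as.vector(uni))), 3L)  # one colour, 3 channels
  # a map attaining the set extrema renders identically local vs global
  loc <- render_heatmap(m1, scaling = "local")[[1]]
  glob_same <- render_heatmap(list(m1), scaling = "global")[[1]]
  expect_equal(loc, glob_same)
  # global scaling pushes the 10x-dimmer map into the bottom of the range
  glob <- render_heatmap(list(m1, m2), scaling = "global")
  rng <- attr(glob[[1]], "range")
  expect_equal(rng, range(c(m1$E, m2$E)))
  frac1 <- (max(m1$E) - rng[1]) / diff(rng)
  expect_lt(frac1, 0.1)
})

test_that("modulus summaries match order statistics", {
  s <- summarize_moduli(c(1, 2, 3, 4, 5) * 1e3)
  expect_equal(s$median, 3e3)
  expect_equal(s$q25, 2e3)
  expect_equal(s$q75, 4e3)
  expect_equal(s$min, 1e3)
  expect_equal(s$max, 5e3)
  one <- summarize_moduli(4330)
  expect_true(all(unlist(one[c("mean", "median", "q25", "q75", "min", "max")]) == 4330))
  expect_error(summarize_moduli(numeric(0)), "no finite")
  # brute-force agreement on a random draw
  set.seed(12)
  v <- rlnorm(101, log(4000), 0.5)
  s2 <- summarize_moduli(v)
  sv <- sort(v)
  expect_equal(s2$min, sv[1])
  expect_equal(s2$max, sv[101])
  expect_equal(s2$median, sv[51])
  expect_equal(s2$mean, sum(v) / 101)
})

test_that("hotspot mixtures pull the mean above the median", {
  maps <- gen_force_map_grid(base_E = 4330, hotspot_factor = 10,
                             hotspot_fraction = 1 / 15, n_maps = 60L,
                             cfg = sim_config(13))
  truths <- unlist(lapply(maps, function(m) m$truth$E_grid))
  s <- summarize_moduli(truths)
  expect_equal(s$max, 43300)
  expect_gt(s$mean, s$median)
})
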