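# Nucleus detection, linking, migration metrics, turn angles, projections.

test_that("nuclei are detected at their true positions", {
  set.seed(41)
  sites <- expand.grid(r = seq(30, 220, by = 27), c = seq(30, 220, by = 27))
  pos <- as.matrix(sites[sample(nrow(sites), 10), ])
  frame <- mechanoquant:::render_spots(256, 256, pos[, 1], pos[, 2], sigma = 3)
  det <- detect_nuclei(frame)
  expect_equal(nrow(det), 10L)
  ord <- order(det$y * 1000 + det$x)
  tru <- order(pos[, 1] * 1000 + pos[, 2])
  expect_true(all(abs(det$y[ord] - pos[tru, 1]) < 1))
  expect_true(all(abs(det$x[ord] - pos[tru, 2]) < 1))
  expect_equal(nrow(detect_nuclei(matrix(0, 64, 64))), 0L)
  # two merged nuclei collapse to one outsized component
  merged <- mechanoquant:::render_spots(128, 128, c(60, 66), c(60, 64), sigma = 3)
  dm <- detect_nuclei(merged)
  expect_equal(nrow(dm), 1L)
  expect_gt(dm$area, median(det$area) * 1.5)
})

test_that("well-separated simulated tracks are linked with full identity", {
  g <- gen_tracks(n_cells = 9, n_frames = 10, migrating_fraction = 1,
                  speed = 0.3, field_size = 600, cfg = sim_config(42))
  # force wide separation: lay cells on a grid
  tr <- g$tracks
  tr$x <- tr$x - ave(tr$x, tr$cell, FUN = function(v) v[1]) +
    150 * ((tr$cell - 1) %% 3) + 100
  tr$y <- tr$y - ave(tr$y, tr$cell, FUN = function(v) v[1]) +
    150 * ((tr$cell - 1) %/% 3) + 100
  dets <- lapply(split(tr, tr$t), function(d)
    d[sample(nrow(d)), c("x", "y")])
  linked <- link_tracks(dets, dt = 15, max_step = 20)
  expect_equal(length(unique(linked$cell)), 9L)
  expect_true(all(table(linked$cell) == 10L))
  # each linked track matches one true track pointwise
  for (id in unique(linked$cell)) {
    lt <- linked[linked$cell == id, ]
    start <- lt[1, c("x", "y")]
    truth <- tr[tr$t == 0 & abs(tr$x - start$x) < 1e-9 &
                  abs(tr$y - start$y) < 1e-9, "cell"]
    tt <- tr[tr$cell == truth, ]
    expect_equal(lt$x, tt$x)
    expect_equal(lt$y, tt$y)
  }
})

test_that("linking is independent of detection order and handles statics", {
  set.seed(43)
  pos <- data.frame(x = c(50, 120, 200), y = c(60, 140, 80))
  frames1 <- lapply(1:6, function(f) pos + 0.1 * f)
  frames2 <- lapply(frames1, function(d) d[c(3, 1, 2), ])
  l1 <- link_tracks(frames1, max_step = 5)
  l2 <- link_tracks(frames2, max_step = 5)
  key <- function(l) {
    s <- split(l[, c("t", "x", "y")], l$cell)
    s <- lapply(s, function(d) {
      d <- d[order(d$t), ]
      rownames(d) <- NULL
      d
    })
    unname(s[order(vapply(s, function(d) d$x[1], 0))])
  }
  expect_equal(key(l1), key(l2))
  single <- link_tracks(lapply(1:8, function(f) data.frame(x = 100, y = 100)),
                        max_step = 5)
  expect_equal(length(unique(single$cell)), 1L)
  expect_equal(migration_metrics(single[, c("t", "x", "y")])$max_displacement, 0)
})

test_that("migration metrics satisfy their defining identities", {
  # ballistic: 0.5 um/min for 14 h
  t <- seq(0, 840, by = 15)
  ball <- data.frame(t = t, x = 0.5 * t, y = 0)
  m <- migration_metrics(ball)
  expect_equal(m$max_displacement, 420)
  expect_equal(m$path_length, 420)
  expect_equal(m$mean_speed, 30)   # um/h
  expect_true(m$migrating)
  # out-and-back: max displacement attained mid-track
  ob <- data.frame(t = c(0, 10, 20), x = c(0, 30, 0), y = 0)
  mo <- migration_metrics(ob)
  expect_equal(mo$max_displacement, 30)
  expect_equal(mo$path_length, 60)
  expect_false(mo$migrating)
  expect_error(migration_metrics(data.frame(t = 0, x = 0, y = 0)), "2 samples")
})

test_that("the migration threshold is strict: exactly 50 um is non-migrating", {
  at50 <- data.frame(t = c(0, 15), x = c(0, 50), y = c(0, 0))
  expect_false(migration_metrics(at50)$migrating)
  over <- data.frame(t = c(0, 15), x = c(0, 50.0001), y = c(0, 0))
  expect_true(migration_metrics(over)$migrating)
  # alternative cell-diameter classifier
  m <- migration_metrics(over, cell_diameter = 30)
  expect_false(m$migrating)
  expect_equal(m$threshold_used, 60)
})

test_that("max displacement never exceeds path length and metrics are rigid-motion invariant", {
  set.seed(44)
  for (k in 1:200) {
    n <- sample(3:30, 1)
    tr <- data.frame(t = seq(0, by = 15, length.out = n),
                     x = cumsum(rnorm(n, 0, 5)), y = cumsum(rnorm(n, 0, 5)))
    m <- migration_metrics(tr)
    expect_lte(m$max_displacement, m$path_length + 1e-12)
  }
  tr <- data.frame(t = seq(0, 150, by = 15),
                   x = cumsum(rnorm(11, 0, 8)), y = cumsum(rnorm(11, 0, 8)))
  m0 <- migration_metrics(tr)
  a <- 0.7
  rot <- data.frame(t = tr$t, x = cos(a) * tr$x - sin(a) * tr$y + 100,
                    y = sin(a) * tr$x + cos(a) * tr$y - 40)
  m1 <- migration_metrics(rot)
  expect_equal(m1$max_displacement, m0$max_displacement)
  expect_equal(m1$path_length, m0$path_length)
})

test_that("percent migrating matches a label-based brute-force count", {
  g <- gen_tracks(n_cells = 120, cfg = sim_config(45))
  pm <- percent_migrating(g$tracks)
  per_cell <- split(g$tracks, g$tracks$cell)
  brute <- mean(vapply(per_cell, function(p) {
    max(sqrt((p$x - p$x[1])^2 + (p$y - p$y[1])^2)) > 50
  }, TRUE)) * 100
  expect_equal(pm$percent, brute)
  # all static / all ballistic extremes
  stat <- gen_tracks(n_cells = 15, migrating_fraction = 0, cfg = sim_config(46))
  expect_equal(percent_migrating(stat$tracks)$percent, 0)
  ball <- gen_tracks(n_cells = 15, migrating_fraction = 1, persistence = 1,
                     cfg = sim_config(47))
  expect_equal(percent_migrating(ball$tracks)$percent, 100)
  expect_error(percent_migrating(data.frame()), "no tracks")
})

test_that("turn angles follow the planar geometry", {
  expect_equal(turn_angle(c(1, 0), c(2, 0))$theta, 0)
  expect_equal(turn_angle(c(1, 0), c(0, 3))$theta, 90)
  expect_equal(turn_angle(c(1, 1), c(-1, -1))$theta, 180)
  # symmetric under left/right reflection
  expect_equal(turn_angle(c(1, 0), c(1, 1))$theta,
               turn_angle(c(1, 0), c(1, -1))$theta)
  expect_error(turn_angle(c(0, 0), c(1, 0)), "non-zero")
})

test_that("stretched populations are distinguished from controls by rank test", {
  g <- gen_durotaxis_assay(cfg = sim_config(48))
  th <- vapply(seq_len(nrow(g$assay)), function(i)
    turn_angle(c(g$assay$before_x[i], g$assay$before_y[i]),
               c(g$assay$after_x[i], g$assay$after_y[i]))$theta, 0)
  s <- th[g$assay$group == "stretched"]
  ctl <- th[g$assay$group == "control"]
  expect_gt(mean(s), mean(ctl))
  expect_lt(stats::wilcox.test(s, ctl)$p.value, 0.01)
})

test_that("track directions feed turn angles from trajectories", {
  tr <- data.frame(t = seq(0, 150, 15),
                   x = c(0, 10, 20, 30, 40, 50, 50, 50, 50, 50, 50),
                   y = c(0, 0, 0, 0, 0, 0, 10, 20, 30, 40, 50))
  before <- track_direction(tr, at_time = 75, side = "before")
  after <- track_direction(tr, at_time = 75, side = "after")
  expect_equal(turn_angle(before, after)$theta, 90)
})

test_that("colour-coded projections encode time and reject empty input", {
  tr <- data.frame(cell = 1, t = rep(seq(0, 90, 15), each = 1),
                   x = seq(20, 90, length.out = 7), y = rep(40, 7))
  img <- color_coded_projection(tr, image_size = c(128L, 128L), radius = 1)
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(64, "plasma"))) / 255
  expect_equal(img[40, 20, ], unname(pal[1, ]))          # first frame colour
  expect_equal(img[40, 90, ], unname(pal[64, ]))         # last frame colour
  expect_error(color_coded_projection(list()), "empty")
  expect_error(color_coded_projection(data.frame(cell = 1, t = 0, x = 1, y = 1),
                                      image_size = c(32L, 32L)), "2 frames")
})
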