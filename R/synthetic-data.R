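# Synthetic-data generators.  Every generator consumes a sim_config and
# emits, next to the observable, a GroundTruth list sufficient to score the
# downstream estimator without re-deriving anything.  All randomness flows
# through a private RNG stream seeded from the config; identical configs give
# bit-identical output, and noise_sd = 0 gives the noiseless analytic
# skeleton.

#' Generate a synthetic AFM force curve
#'
#' Samples an approach curve that is flat (noise only) before the contact
#' point and follows the spherical-indenter Hertz law [hertz_force()] beyond
#' it. Defaults mirror a 5 um borosilicate sphere probe on a 0.06 N/m
#' cantilever indenting soft tissue (the peritoneum-like default modulus is
#' 4.33 kPa). For force curves `cfg$noise_sd` is interpreted *relative to the
#' curve's maximum force* (e.g. 0.02 = 2 percent force noise), so one
#' setting is meaningful across moduli.
#'
#' @param E True Young's modulus, Pa.
#' @param probe_radius Probe sphere radius, um.
#' @param poisson Poisson ratio.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param contact_offset Piezo position of the contact point, um.
#' @param max_indentation Maximum indentation depth sampled, um.
#' @param n_samples Number of samples along the approach.
#' @param cfg A [sim_config()].
#'
#' @return List: `curve` (a [force_curve()]), `truth` (list with `E`,
#'   `contact_point`, `noise_sd_nN`).
#' @export
gen_force_curve <- function(E = 4330, probe_radius = 2.5, poisson = 0.5,
                            spring_constant = 0.06, contact_offset = 0.5,
                            max_indentation = 1.5, n_samples = 400L,
                            cfg = sim_config()) {
  check_scalar(E, "E", 0, strict_lower = TRUE)
  check_scalar(probe_radius, "probe_radius", 0, strict_lower = TRUE)
  check_scalar(contact_offset, "contact_offset", 0)
  with_seed(cfg$seed, {
    z <- seq(0, contact_offset + max_indentation, length.out = n_samples)
    delta <- pmax(z - contact_offset, 0)
    f <- hertz_force(E, delta, probe_radius, poisson)
    noise_nN <- cfg$noise_sd * max(f)
    if (noise_nN > 0) f <- f + stats::rnorm(n_samples, 0, noise_nN)
    list(curve = force_curve(z, force = f, probe_radius = probe_radius,
                             poisson = poisson,
                             spring_constant = spring_constant,
                             metadata = list(probe_speed_um_s = 10,
                                             retraction_um = 5)),
         truth = list(E = E, contact_point = contact_offset,
                      noise_sd_nN = noise_nN))
  })
}

#' Generate force-map grids with sparse stiffness hotspots
#'
#' Emulates tissue force mapping: each map is an 8 x 8 grid of force curves
#' over a 20 x 20 um region at a soft background modulus; with probability
#' `hotspot_fraction` a map's moduli are multiplied by `hotspot_factor`
#' (sparse ~10x stiffness hotspots, by default ~1 map in 15).
#'
#' @param base_E Background Young's modulus, Pa (default 4330).
#' @param hotspot_factor Multiplier for hotspot maps (>= 1).
#' @param hotspot_fraction Probability a map is a hotspot, in `[0, 1]`.
#' @param n_maps Number of maps.
#' @param shape Grid dimensions per map.
#' @param region_size Mapped region side, um.
#' @param cfg A [sim_config()]; `noise_sd` is passed to the per-point curves.
#' @inheritParams gen_force_curve
#'
#' @return List of per-map lists: `curves` (row-major list of
#'   [force_curve()]), `truth` (list with `E_grid` matrix Pa and `hotspot`
#'   flag).
#' @export
gen_force_map_grid <- function(base_E = 4330, hotspot_factor = 10,
                               hotspot_fraction = 1 / 15, n_maps = 15L,
                               shape = c(8L, 8L), region_size = 20,
                               contact_offset = 0.5, cfg = sim_config()) {
  check_scalar(hotspot_fraction, "hotspot_fraction", 0, 1)
  check_scalar(hotspot_factor, "hotspot_factor", 1)
  with_seed(cfg$seed, {
    lapply(seq_len(n_maps), function(m) {
      hot <- stats::runif(1) < hotspot_fraction
      Eg <- matrix(base_E * if (hot) hotspot_factor else 1, shape[1], shape[2])
      curves <- lapply(seq_len(prod(shape)), function(i) {
        sub <- sim_config(seed = stats::runif(1, 1, 2^30), noise_sd = cfg$noise_sd)
        gen_force_curve(E = Eg[i], contact_offset = contact_offset,
                        cfg = sub)$curve
      })
      list(curves = curves, truth = list(E_grid = Eg, hotspot = hot))
    })
  })
}

#' Contractile-dipole traction field
#'
#' Parametric traction pattern used for TFM fixtures: two Gaussian-tapered
#' circular patches pulling toward each other (a force dipole, net force
#' zero by symmetry), the canonical idealization of a contractile cell.
#'
#' @param image_size `c(rows, cols)` of the pixel grid.
#' @param pixel_size Pixel size, um.
#' @param peak Peak traction magnitude, Pa.
#' @param patch_sigma Gaussian patch radius parameter, um.
#' @param separation Centre-to-centre distance of the two patches, um.
#'
#' @return A [traction_field()] on the pixel grid (spacing = pixel size).
#' @export
traction_dipole <- function(image_size = c(512L, 512L), pixel_size = 0.161,
                            peak = 2000, patch_sigma = 4, separation = 30) {
  nr <- image_size[1]; nc <- image_size[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * pixel_size
  y <- (seq_len(nr) - (nr + 1) / 2) * pixel_size
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  g <- function(cx) exp(-((X - cx)^2 + Y^2) / (2 * patch_sigma^2))
  # left patch pulls right (+x), right patch pulls left (-x): contraction
  tx <- peak * (g(-separation / 2) - g(separation / 2))
  tx[abs(tx) < 1e-8 * peak] <- 0     # compact support (exact far-field zero)
  ty <- matrix(0, nr, nc)
  traction_field(tx, ty, spacing_um = pixel_size)
}

#' Render a bead image
#'
#' Diffraction-limited fluorescent beads rendered as 2D Gaussian spots on a
#' dark background, with optional Gaussian camera noise.
#'
#' @param positions Two-column matrix of bead centres `(row, col)`, px
#'   (subpixel allowed).
#' @param image_size `c(rows, cols)`.
#' @param bead_sigma Spot Gaussian sigma, px.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param baseline Constant background offset.
#'
#' @return Image matrix.
#' @export
render_bead_image <- function(positions, image_size = c(512L, 512L),
                              bead_sigma = 1.5, noise_sd = 0,
                              baseline = 0.02) {
  img <- render_spots(image_size[1], image_size[2],
                      positions[, 1], positions[, 2], sigma = bead_sigma) +
    baseline
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        image_size[1], image_size[2])
  }
  img
}

#' Generate a TFM bead-image pair with known traction
#'
#' Builds a reference (zero-force) bead image and a deformed image in which
#' every bead has moved by the forward Boussinesq displacement
#' ([forward_displacement()]) of a known traction field, sampled at the bead
#' position. `cfg$noise_sd` is camera noise in intensity units (spot peak =
#' 1). An optional rigid `drift` (px) is applied to the deformed frame to
#' exercise registration.
#'
#' @param traction A [traction_field()] on the pixel grid (e.g.
#'   [traction_dipole()]); should be balanced (near-zero net force).
#' @param substrate An [elastic_substrate()].
#' @param bead_density Beads per um^2 (default 0.3).
#' @param image_size `c(rows, cols)`, px.
#' @param bead_sigma Spot sigma, px.
#' @param drift `c(drow, dcol)` rigid drift of the deformed frame, px.
#' @param cfg A [sim_config()].
#'
#' @return List: `reference`, `deformed` (matrices), `truth` (list with
#'   `ux`, `uy` pixel-grid displacement in px, `traction`, `bead_positions`),
#'   `substrate`.
#' @export
gen_tfm_pair <- function(traction, substrate, bead_density = 0.3,
                         image_size = c(512L, 512L), bead_sigma = 1.5,
                         drift = c(0, 0), cfg = sim_config()) {
  stopifnot(inherits(traction, "traction_field"),
            inherits(substrate, "elastic_substrate"))
  nr <- image_size[1]; nc <- image_size[2]
  if (nrow(traction$tx) != nr || ncol(traction$tx) != nc) {
    stop("traction grid must match `image_size`", call. = FALSE)
  }
  net <- c(sum(traction$tx), sum(traction$ty)) * traction$spacing_um^2
  total <- sum(traction$magnitude) * traction$spacing_um^2
  if (total > 0 && sqrt(sum(net^2)) > 1e-3 * total) {
    warning("traction field is not force-balanced; displacement far field ",
            "will not decay cleanly", call. = FALSE)
  }
  disp <- forward_displacement(traction, substrate)
  ux_px <- disp$ux / substrate$pixel_size
  uy_px <- disp$uy / substrate$pixel_size
  max_u <- max(sqrt(ux_px^2 + uy_px^2))
  if (max_u > 0.1 * min(nr, nc)) {
    warning(sprintf("peak displacement %.1f px exceeds 10%% of the image; ",
                    max_u), "PIV search windows may fail", call. = FALSE)
  }
  with_seed(cfg$seed, {
    area_um2 <- nr * nc * substrate$pixel_size^2
    n_beads <- stats::rpois(1, bead_density * area_um2)
    pos <- cbind(stats::runif(n_beads, 1, nr), stats::runif(n_beads, 1, nc))
    ref <- render_bead_image(pos, image_size, bead_sigma, cfg$noise_sd)
    bead_ux <- bilinear_at(ux_px, pos[, 1], pos[, 2])
    bead_uy <- bilinear_at(uy_px, pos[, 1], pos[, 2])
    moved <- cbind(pos[, 1] + bead_uy + drift[1], pos[, 2] + bead_ux + drift[2])
    def <- render_bead_image(moved, image_size, bead_sigma, cfg$noise_sd)
    list(reference = ref, deformed = def,
         truth = list(ux = ux_px, uy = uy_px, traction = traction,
                      bead_positions = pos, drift = drift),
         substrate = substrate)
  })
}

#' Generate cell tracks with a known migrating fraction
#'
#' Migrating cells follow a persistent random walk (step direction correlated
#' between frames; `persistence` in `[0, 1]` maps to a wrapped-normal turning
#' noise with SD `(1 - persistence) * pi` radians). Non-migrating cells
#' jitter around their seeding point with a scale far below the 50 um
#' migration threshold. Defaults (`dt` 15 min, 57 frames = 14 h; speed 0.35
#' um/min, persistence 0.8) give migrating cells a mean maximum displacement
#' around 125 um and make them exceed 50 um with probability above 0.99.
#'
#' @param n_cells Number of cells.
#' @param n_frames Frames per track.
#' @param dt Frame interval, minutes.
#' @param speed Migrating-cell speed, um/min.
#' @param persistence Directional persistence in `[0, 1]` (1 = ballistic).
#' @param migrating_fraction Probability a cell is a migrator.
#' @param jitter_sd Positional jitter SD of non-migrating cells, um.
#' @param field_size Side of the square seeding region, um.
#' @param cfg A [sim_config()].
#'
#' @return List: `tracks` (long data.frame `cell`, `t`, `x`, `y`), `truth`
#'   (data.frame `cell`, `migrating`).
#' @export
gen_tracks <- function(n_cells = 200L, n_frames = 57L, dt = 15,
                       speed = 0.35, persistence = 0.8,
                       migrating_fraction = 0.45, jitter_sd = 1,
                       field_size = 800, cfg = sim_config()) {
  check_scalar(migrating_fraction, "migrating_fraction", 0, 1)
  check_scalar(persistence, "persistence", 0, 1)
  with_seed(cfg$seed, {
    migrating <- stats::runif(n_cells) < migrating_fraction
    step <- speed * dt
    sd_ang <- (1 - persistence) * pi
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      x0 <- stats::runif(1, 0, field_size)
      y0 <- stats::runif(1, 0, field_size)
      if (migrating[i]) {
        th <- stats::runif(1, 0, 2 * pi) +
          cumsum(c(0, stats::rnorm(n_frames - 2L, 0, sd_ang)))
        x <- x0 + cumsum(c(0, step * cos(th)))
        y <- y0 + cumsum(c(0, step * sin(th)))
      } else {
        x <- x0 + stats::rnorm(n_frames, 0, jitter_sd)
        y <- y0 + stats::rnorm(n_frames, 0, jitter_sd)
        x[1] <- x0; y[1] <- y0
      }
      rows[[i]] <- data.frame(cell = i, t = (seq_len(n_frames) - 1) * dt,
                              x = x, y = y)
    }
    list(tracks = do.call(rbind, rows),
         truth = data.frame(cell = seq_len(n_cells), migrating = migrating))
  })
}

#' Generate a durotaxis turn-angle assay
#'
#' Direction pairs (before the stimulus; 75 minutes after) for a stretched
#' population that turns toward an orthogonal durotactic stimulus and an
#' unstimulated control population that only wanders. Turn magnitudes are
#' folded normals: control SD `control_sd` about 0; stretched centred on
#' `stretch_mean` (toward the stimulus side, sign random per cell).
#'
#' @param n_stretched,n_control Cells per group.
#' @param stretch_mean Mean stretched turn angle, degrees.
#' @param stretch_sd,control_sd Turn-angle SDs, degrees.
#' @param evaluation_delay Minutes between the two directions (metadata).
#' @param cfg A [sim_config()].
#'
#' @return List: `assay` (data.frame `group`, `before_x`, `before_y`,
#'   `after_x`, `after_y`), `truth` (list `mean_theta_stretched`,
#'   `mean_theta_control` of the realized angles).
#' @export
gen_durotaxis_assay <- function(n_stretched = 20L, n_control = 20L,
                                stretch_mean = 75, stretch_sd = 20,
                                control_sd = 15, evaluation_delay = 75,
                                cfg = sim_config()) {
  with_seed(cfg$seed, {
    rotate <- function(v, deg) {
      a <- deg * pi / 180
      c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
    }
    make_group <- function(n, angles) {
      t(vapply(seq_len(n), function(i) {
        phi <- stats::runif(1, 0, 2 * pi)
        before <- c(cos(phi), sin(phi))
        after <- rotate(before, angles[i])
        c(before, after)
      }, numeric(4)))
    }
    ang_s <- sample(c(-1, 1), n_stretched, TRUE) *
      abs(stats::rnorm(n_stretched, stretch_mean, stretch_sd))
    ang_c <- stats::rnorm(n_control, 0, control_sd)
    gs <- make_group(n_stretched, ang_s)
    gc <- make_group(n_control, ang_c)
    assay <- data.frame(
      group = rep(c("stretched", "control"), c(n_stretched, n_control)),
      before_x = c(gs[, 1], gc[, 1]), before_y = c(gs[, 2], gc[, 2]),
      after_x = c(gs[, 3], gc[, 3]), after_y = c(gs[, 4], gc[, 4]))
    list(assay = assay,
         truth = list(mean_theta_stretched = mean(abs(ang_s)),
                      mean_theta_control = mean(abs(ang_c)),
                      evaluation_delay = evaluation_delay))
  })
}

# Smoothly irregular disk mask: radius r(phi) = r * (1 + irregularity *
# low-order Fourier perturbation), centred at (cy, cx).
irregular_disk_mask <- function(nr, nc, cy, cx, r, irregularity = 0.05) {
  a <- stats::rnorm(3, 0, 1); b <- stats::rnorm(3, 0, 1)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  Y <- matrix(seq_len(nr), nr, nc) - cy
  phi <- atan2(Y, X)
  pert <- matrix(0, nr, nc)
  for (k in 1:3) pert <- pert + a[k] * cos(k * phi) + b[k] * sin(k * phi)
  pert <- pert / sqrt(sum(a^2 + b^2) / 2 + 1e-12)   # unit-RMS perturbation
  sqrt(X^2 + Y^2) <= r * (1 + irregularity * pert)
}

#' Generate a spheroid image pair with known area fold-change
#'
#' Two phase-contrast-like images of one spheroid: an initial compact
#' footprint of radius about `r0` and a later footprint whose area is
#' `area_fold` times larger, both with smoothly irregular boundaries and a
#' speckled interior texture over a flat background. The truth areas are the
#' exact pixel counts of the rendered masks.
#'
#' @param r0 Initial footprint radius, px.
#' @param area_fold Target area fold-change (>= 1).
#' @param image_size `c(rows, cols)`.
#' @param irregularity Relative boundary perturbation amplitude.
#' @param cfg A [sim_config()]; `noise_sd` is camera noise (intensity units).
#'
#' @return List: `initial`, `final` (image matrices), `truth` (list
#'   `area_initial`, `area_final` px^2, `fold`, `mask_initial`,
#'   `mask_final`).
#' @export
gen_spheroid_pair <- function(r0 = 60, area_fold = 6.6,
                              image_size = c(512L, 512L),
                              irregularity = 0.04, cfg = sim_config()) {
  check_scalar(area_fold, "area_fold", 1)
  nr <- image_size[1]; nc <- image_size[2]
  r1 <- r0 * sqrt(area_fold)
  if (r1 * (1 + 3 * irregularity) >= min(nr, nc) / 2 - 2) {
    stop("spheroid does not fit in the frame at the requested fold", call. = FALSE)
  }
  with_seed(cfg$seed, {
    render <- function(r) {
      mask <- irregular_disk_mask(nr, nc, (nr + 1) / 2, (nc + 1) / 2, r,
                                  irregularity)
      img <- matrix(0.2, nr, nc)
      img[mask] <- 0.55 + stats::runif(sum(mask), 0, 0.25)  # speckled interior
      if (cfg$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
      }
      list(img = img, mask = mask)
    }
    t0 <- render(r0)
    t1 <- render(r1)
    list(initial = t0$img, final = t1$img,
         truth = list(area_initial = sum(t0$mask), area_final = sum(t1$mask),
                      fold = sum(t1$mask) / sum(t0$mask),
                      mask_initial = t0$mask, mask_final = t1$mask))
  })
}

#' Generate a two-channel colocalization fixture
#'
#' Gaussian spots placed on a coarse exclusion grid so that spot supports
#' never overlap unless shared: a fraction `overlap` of channel-B spots sit
#' exactly on channel-A spots, the rest on disjoint sites. The expected
#' Manders coefficients (threshold 0, noiseless) are computed from the
#' rendered images and the true shared-support masks.
#'
#' @param overlap Fraction of shared spot sites, in `[0, 1]`.
#' @param image_size `c(rows, cols)`.
#' @param n_spots Spots per channel.
#' @param spot_sigma Spot Gaussian sigma, px.
#' @param cfg A [sim_config()]; `noise_sd` adds camera noise.
#'
#' @return List: `channel_a`, `channel_b` (matrices), `truth` (list `m1`,
#'   `m2`, `overlap`, `support_a`, `support_b` logical masks).
#' @export
gen_coloc_images <- function(overlap = 0.5, image_size = c(256L, 256L),
                             n_spots = 40L, spot_sigma = 2.5,
                             cfg = sim_config()) {
  check_scalar(overlap, "overlap", 0, 1)
  nr <- image_size[1]; nc <- image_size[2]
  cell <- ceiling(9 * spot_sigma)          # exclusion grid pitch
  gr <- floor((nr - cell) / cell); gc <- floor((nc - cell) / cell)
  n_shared <- round(overlap * n_spots)
  n_sites <- 2L * n_spots - n_shared
  if (n_sites > gr * gc) stop("too many spots for the image size", call. = FALSE)
  with_seed(cfg$seed, {
    sites <- sample(gr * gc, n_sites)
    sr <- ((sites - 1) %% gr) * cell + cell / 2 + cell / 2 +
      stats::runif(n_sites, -1, 1)
    sc <- ((sites - 1) %/% gr) * cell + cell / 2 + cell / 2 +
      stats::runif(n_sites, -1, 1)
    shared <- seq_len(n_shared)
    a_only <- seq_len(n_spots - n_shared) + n_shared
    b_only <- seq_len(n_spots - n_shared) + n_spots
    idx_a <- c(shared, a_only)
    idx_b <- c(shared, b_only)
    a <- render_spots(nr, nc, sr[idx_a], sc[idx_a], sigma = spot_sigma)
    b <- render_spots(nr, nc, sr[idx_b], sc[idx_b], sigma = spot_sigma)
    m1 <- sum(a[b > 0]) / sum(a)
    m2 <- sum(b[a > 0]) / sum(b)
    support_a <- a > 0
    support_b <- b > 0
    if (cfg$noise_sd > 0) {
      a <- pmax(a + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc), 0)
      b <- pmax(b + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc), 0)
    }
    list(channel_a = a, channel_b = b,
         truth = list(m1 = m1, m2 = m2, overlap = overlap,
                      support_a = support_a, support_b = support_b))
  })
}

#' Generate a cell image with known nuclear:cytoplasmic ratio
#'
#' A disk-shaped cell with a concentric disk nucleus; the signal is uniform
#' at `cyto_level` in the cytoplasm and `ratio * cyto_level` in the nucleus,
#' so the noiseless estimator recovers `ratio` exactly.
#'
#' @param ratio True nuclear:cytoplasmic ratio (> 0).
#' @param image_size `c(rows, cols)`.
#' @param cell_radius,nuc_radius Radii, px.
#' @param cyto_level Cytoplasmic signal level.
#' @param cfg A [sim_config()]; `noise_sd` adds Gaussian noise.
#'
#' @return List: `signal` (matrix), `nuclear_mask`, `cell_mask` (logical
#'   matrices), `truth` (list `ratio`).
#' @export
gen_nc_cell <- function(ratio = 2, image_size = c(128L, 128L),
                        cell_radius = 50, nuc_radius = 16, cyto_level = 0.3,
                        cfg = sim_config()) {
  check_scalar(ratio, "ratio", 0, strict_lower = TRUE)
  nr <- image_size[1]; nc <- image_size[2]
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - (nc + 1) / 2
  Y <- matrix(seq_len(nr), nr, nc) - (nr + 1) / 2
  r2 <- X^2 + Y^2
  cell <- r2 <= cell_radius^2
  nucl <- r2 <= nuc_radius^2
  sig <- matrix(0, nr, nc)
  sig[cell] <- cyto_level
  sig[nucl] <- ratio * cyto_level
  with_seed(cfg$seed, {
    if (cfg$noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
    }
    list(signal = sig, nuclear_mask = nucl, cell_mask = cell,
         truth = list(ratio = ratio))
  })
}
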