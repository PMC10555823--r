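# Deterministic synthetic-data generators for every test input: stage
# phantoms, tilted/offset tile frames, complete montage datasets with mdoc
# metadata, and fringed beam images.  Every generator is a pure function of
# (seed, config); the same seed reproduces byte-identical outputs.
#
# Desk-scale defaults (frames of ~100 px, 21 tilts) keep full-pipeline tests
# fast; full-size frame generation is supported but not the default.

#' Desk-scale camera frame
#'
#' A small frame sharing the benchmark aspect ratio, sampled so that a
#' 512-pixel phantom spans 10 um (195.3 A per pixel).
#'
#' @param width_px,height_px Frame size in pixels.
#' @param pixel_size_A Sampling, Angstrom per pixel.
#' @return A [camera_frame()].
#' @export
desk_camera_frame <- function(width_px = 128, height_px = 96,
                              pixel_size_A = 1e5 / 512) {
  camera_frame(width_px, height_px, pixel_size_A)
}

#' Bilinear sampling of a matrix at fractional indices
#'
#' @param img Matrix `[x, y]`.
#' @param xs,ys Fractional 1-based indices along each axis.
#' @param background Value outside the image.
#' @return Matrix `length(xs) x length(ys)`.
#' @keywords internal
bilinear_sample <- function(img, xs, ys, background = 0) {
  nx <- nrow(img); ny <- ncol(img)
  i0 <- floor(xs); fx <- xs - i0
  j0 <- floor(ys); fy <- ys - j0
  vx <- i0 >= 1 & i0 + 1 <= nx
  vy <- j0 >= 1 & j0 + 1 <= ny
  i0c <- pmin(pmax(i0, 1), nx - 1)
  j0c <- pmin(pmax(j0, 1), ny - 1)
  out <- img[i0c, j0c, drop = FALSE] * outer(1 - fx, 1 - fy) +
    img[i0c + 1, j0c, drop = FALSE] * outer(fx, 1 - fy) +
    img[i0c, j0c + 1, drop = FALSE] * outer(1 - fx, fy) +
    img[i0c + 1, j0c + 1, drop = FALSE] * outer(fx, fy)
  out[!vx, ] <- background
  out[, !vy] <- background
  out
}

um_to_index <- function(u_um, n, extent_um) (u_um / extent_um + 0.5) * n + 0.5

#' Synthetic stage phantom
#'
#' A flat background carrying a high-contrast central region of interest
#' (two "wing" ellipses spanning 5 x 4 um, emulating an extended cellular
#' target) and Gaussian point features at known positions.  The phantom is
#' the specimen-plane ground truth every rendered tile is cut from.
#'
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param nx,ny Phantom size in pixels.
#' @param extent_um Physical extent `c(x, y)`.
#' @param n_points Number of random point features.
#' @param background Background intensity.
#' @param roi Include the central extended ROI.
#' @return List of class `phantom`: `image` (`[x, y]` matrix),
#'   `pixel_size_A`, `extent_um`, `features` (data frame `x_um`, `y_um`),
#'   `roi_extent_um`.
#' @export
make_phantom <- function(seed = 1, nx = 512, ny = 512, extent_um = c(10, 10),
                         n_points = 60, background = 100, roi = TRUE) {
  set.seed(seed)
  img <- matrix(background, nx, ny)
  xs <- ((seq_len(nx) - 0.5) / nx - 0.5) * extent_um[1]
  ys <- ((seq_len(ny) - 0.5) / ny - 0.5) * extent_um[2]
  if (roi) {
    # two wings spanning 5 um in x and 4 um in y, centred on the origin
    for (sgn in c(-1, 1)) {
      u <- (xs - sgn * 1.25) / 1.25
      v <- ys / 2
      wing <- outer(u^2, v^2, `+`) <= 1
      img[wing] <- img[wing] + 80
    }
    body <- outer(abs(xs) <= 0.25, abs(ys) <= 1.5, `&`)
    img[body] <- img[body] + 40
  }
  feats <- data.frame(
    x_um = stats::runif(n_points, -0.4 * extent_um[1], 0.4 * extent_um[1]),
    y_um = stats::runif(n_points, -0.4 * extent_um[2], 0.4 * extent_um[2])
  )
  px_per_um <- nx / extent_um[1]
  sig <- 1.5
  for (f in seq_len(nrow(feats))) {
    ci <- um_to_index(feats$x_um[f], nx, extent_um[1])
    cj <- um_to_index(feats$y_um[f], ny, extent_um[2])
    ii <- max(1, floor(ci - 4)):min(nx, ceiling(ci + 4))
    jj <- max(1, floor(cj - 4)):min(ny, ceiling(cj + 4))
    img[ii, jj] <- img[ii, jj] +
      150 * outer(exp(-(ii - ci)^2 / (2 * sig^2)),
                  exp(-(jj - cj)^2 / (2 * sig^2)))
  }
  structure(
    list(image = img, pixel_size_A = extent_um[1] / nx * 1e4,
         extent_um = extent_um, features = feats,
         roi_extent_um = if (roi) c(5, 4) else c(0, 0)),
    class = "phantom"
  )
}

#' Render one camera frame of a tilted, shifted acquisition
#'
#' The frame is the phantom foreshortened by cos(alpha) along y, cropped at
#' the tile's image-plane position (the tile image shift, scaled by
#' cos(alpha) when beam-image-shift compensation is on, plus the beam-frame
#' spiral offset), optionally masked by the beam footprint, with optional
#' Fresnel-fringe ringing at the x edges and Poisson counting noise.
#'
#' @param phantom A [make_phantom()] result.
#' @param alpha_deg Tilt angle.
#' @param tile_shift_um Tile image-shift vector `c(x, y)` (micrometres,
#'   relative to the pattern centre).
#' @param offset_um Beam-frame translational offset `c(dx, dy)` from the
#'   offset table (micrometres).
#' @param frame A [camera_frame()] (desk scale by default).
#' @param beam Optional [beam_illumination()]; when given, pixels outside
#'   the beam disc (image plane) are set to 0.
#' @param fringe Optional list `(depth_fraction, amplitude, period_px)`
#'   adding sinusoidal ringing over the outer x band.
#' @param noise_mean Optional mean background counts per pixel; Poisson
#'   noise is drawn at rate `image / background * noise_mean`.
#' @param compensate Apply the per-tilt compensation to the tile shift.
#' @param seed Seed used when noise is drawn.
#' @return Numeric `width_px x height_px` matrix `[x, y]`.
#' @export
render_tile <- function(phantom, alpha_deg, tile_shift_um = c(0, 0),
                        offset_um = c(0, 0), frame = desk_camera_frame(),
                        beam = NULL, fringe = NULL, noise_mean = NULL,
                        compensate = TRUE, seed = 1) {
  ca <- cospi(alpha_deg / 180)
  px_um <- frame$pixel_size_A * 1e-4
  tsy <- if (compensate) tile_shift_um[2] * ca else tile_shift_um[2]
  cx <- tile_shift_um[1] + offset_um[1]
  cy <- tsy + offset_um[2]
  u <- (seq_len(frame$width_px) - (frame$width_px + 1) / 2) * px_um
  v <- (seq_len(frame$height_px) - (frame$height_px + 1) / 2) * px_um
  xi <- cx + u                 # image-plane coordinates of frame pixels
  yi <- cy + v
  xs <- um_to_index(xi, nrow(phantom$image), phantom$extent_um[1])
  ys <- um_to_index(yi / ca, ncol(phantom$image), phantom$extent_um[2])
  if (max(xs) < 1 || min(xs) > nrow(phantom$image) ||
      max(ys) < 1 || min(ys) > ncol(phantom$image))
    stop("tile fully outside the phantom")
  img <- bilinear_sample(phantom$image, xs, ys, background = 0)
  if (!is.null(beam)) {
    r_um <- beam$diameter_um / 2
    inside <- outer(u^2, v^2, `+`) <= r_um^2
    img[!inside] <- 0
  }
  if (!is.null(fringe)) {
    d <- round(fringe$depth_fraction * frame$width_px)
    if (d > 0) {
      for (side in list(seq_len(d), frame$width_px - seq_len(d) + 1L)) {
        edge_dist <- seq_len(d)
        img[side, ] <- img[side, ] +
          fringe$amplitude * sin(2 * pi * edge_dist / fringe$period_px)
      }
    }
  }
  if (!is.null(noise_mean)) {
    set.seed(seed)
    lam <- pmax(img, 0) / 100 * noise_mean
    img <- matrix(stats::rpois(length(lam), lam), nrow(img), ncol(img))
  }
  img
}

#' Generate a complete synthetic montage dataset
#'
#' Builds a phantom, a grouped dose-symmetric tilt scheme, a clamped spiral
#' offset table and one rendered frame per (tilt, tile), together with mdoc
#' metadata and ground-truth tables.  The defaults are desk scale: a 3 x 3
#' pattern of 128 x 96 px tiles (20 % / 10 % overlaps), 21 tilts at
#' +/-30 deg in 3 deg steps, beam-image-shift compensation on and the
#' benchmark spiral.
#'
#' @param seed RNG seed.
#' @param frame A [camera_frame()].
#' @param pattern A [montage_pattern()]; default derived from `frame` with
#'   20 % / 10 % overlaps.
#' @param scheme A [tilt_scheme()].
#' @param spiral A [spiral_params()]; `NULL` disables offsets.
#' @param mode Offset mode (see [offsets_for_tilts()]).
#' @param noise_mean Optional Poisson noise level (mean background counts).
#' @param compensate Per-tilt beam-image-shift compensation.
#' @param phantom Optional pre-built [make_phantom()].
#' @return Object of class `montage_dataset`: `frames` (list of matrices,
#'   acquisition order), `meta` (data frame: `exposure`, `tilt_index`,
#'   `angle_deg`, `tile`, `ix`, `iy`, `piece_x`, `piece_y`), `frame`,
#'   `pattern`, `scheme`, `offsets`, `mdoc`, `phantom`, and `truth` (exact
#'   per-tilt content piece coordinates).
#' @export
make_montage_dataset <- function(seed = 1, frame = desk_camera_frame(),
                                 pattern = NULL,
                                 scheme = tilt_scheme(30, 3, group_size = 3),
                                 spiral = spiral_params(),
                                 mode = "adjusted",
                                 noise_mean = NULL, compensate = TRUE,
                                 phantom = NULL) {
  if (is.null(pattern)) {
    ov <- overlap_px(frame, 0.20, 0.10)
    pattern <- montage_pattern(3, 3, ov["x"], ov["y"])
  }
  if (is.null(phantom)) phantom <- make_phantom(seed = seed)
  grid <- tile_grid(pattern, frame)
  angles <- generate_tilt_angles(scheme)
  offsets <- if (is.null(spiral)) {
    offsets_for_tilts(data.frame(dx_um = rep(0, length(angles)),
                                 dy_um = rep(0, length(angles))),
                      angles, mode)
  } else {
    spiral_offset_table(spiral, scheme, frame, mode)
  }
  n_exp <- length(angles) * nrow(grid)
  frames <- vector("list", n_exp)
  meta <- vector("list", n_exp)
  truth <- vector("list", length(angles))
  e <- 0L
  for (i in seq_along(angles)) {
    a <- angles[i]
    for (t in seq_len(nrow(grid))) {
      e <- e + 1L
      frames[[e]] <- render_tile(
        phantom, a,
        tile_shift_um = c(grid$shift_x_um[t], grid$shift_y_um[t]),
        offset_um = c(offsets$dx_um[i], offsets$dy_um[i]),
        frame = frame, noise_mean = noise_mean, compensate = compensate,
        seed = seed + e
      )
      meta[[e]] <- data.frame(
        exposure = e, tilt_index = i - 1L, angle_deg = a, tile = t,
        ix = grid$ix[t], iy = grid$iy[t],
        piece_x = grid$piece_x[t], piece_y = grid$piece_y[t]
      )
    }
    pc <- piece_coords_at_tilt(grid, a)
    truth[[i]] <- data.frame(tilt_index = i - 1L, angle_deg = a,
                             tile = pc$tile, piece_x = pc$piece_x,
                             piece_y = pc$piece_y)
  }
  structure(
    list(frames = frames, meta = do.call(rbind, meta), frame = frame,
         pattern = pattern, scheme = scheme, offsets = offsets,
         mdoc = build_montage_mdoc(frame, pattern, scheme),
         phantom = phantom, truth = do.call(rbind, truth)),
    class = "montage_dataset"
  )
}

#' @export
print.montage_dataset <- function(x, ...) {
  cat(sprintf(
    "montage dataset: %d x %d tiles, %d tilts, %d frames of %d x %d px\n",
    x$pattern$m, x$pattern$n, length(unique(x$meta$tilt_index)),
    length(x$frames), x$frame$width_px, x$frame$height_px))
  invisible(x)
}

#' Gain-normalized beam image with fringes of known depth
#'
#' A flat gain-normalized background (Gaussian read-out noise) with
#' sinusoidal ringing superposed over the outer `depth_fraction` of the x
#' dimension from each edge, emulating Fresnel fringes where the beam edge
#' crosses the frame.  The injected depth is the ground truth for
#' calibration round-trip tests.
#'
#' @param seed RNG seed.
#' @param nx,ny Image size in pixels.
#' @param depth_fraction Fringe depth as a fraction of x per side.
#' @param amplitude Fringe amplitude in units of the noise sd.
#' @param noise_sd Gaussian background sd.
#' @param period_px Fringe spatial period in pixels (must survive the 50 A
#'   low-pass used in calibration).
#' @param mean_level Background mean.
#' @param pixel_size_A Sampling recorded for the calibration step.
#' @return List of class `fringed_beam`: `image`, `depth_fraction`,
#'   `pixel_size_A` and generator parameters.
#' @export
make_fringed_beam <- function(seed = 1, nx = 1152, ny = 816,
                              depth_fraction = 0.04, amplitude = 6,
                              noise_sd = 1, period_px = 24,
                              mean_level = 100, pixel_size_A = 4.603) {
  stopifnot(depth_fraction >= 0, depth_fraction < 0.5)
  set.seed(seed)
  img <- matrix(stats::rnorm(nx * ny, mean_level, noise_sd), nx, ny)
  d <- round(depth_fraction * nx)
  if (d > 0) {
    ring <- amplitude * noise_sd * sin(2 * pi * seq_len(d) / period_px)
    img[seq_len(d), ] <- img[seq_len(d), ] + ring
    img[nx - seq_len(d) + 1L, ] <- img[nx - seq_len(d) + 1L, ] + ring
  }
  structure(
    list(image = img, depth_fraction = depth_fraction,
         pixel_size_A = pixel_size_A, amplitude = amplitude,
         noise_sd = noise_sd, period_px = period_px,
         mean_level = mean_level),
    class = "fringed_beam"
  )
}

#' Synthetic particle table with prescribed overdose counts
#'
#' Builds a particle table in which a stated number of particles carry
#' accumulated doses at or above the overdose threshold and the rest below
#' it, with uniformly drawn coordinates.  Used to exercise the dose filter
#' at the scale of a real sub-tomogram data set.
#'
#' @param seed RNG seed.
#' @param n_total Total particle count.
#' @param n_overdosed Particles with dose at or above `threshold`.
#' @param threshold Overdose threshold (electrons per square Angstrom).
#' @param box Source-volume extent `c(x, y, z)` in voxels for coordinates.
#' @return A `particle_table` (see [particle_table()]) with doses annotated.
#' @export
make_particle_fixture <- function(seed = 1, n_total = 13021,
                                  n_overdosed = 3689, threshold = 130,
                                  box = c(928, 928, 464)) {
  stopifnot(n_overdosed <= n_total)
  set.seed(seed)
  dose <- c(stats::runif(n_overdosed, threshold, 2 * threshold),
            stats::runif(n_total - n_overdosed, 0, threshold * (1 - 1e-9)))
  dose <- sample(dose)
  particle_table(
    id = seq_len(n_total),
    tomo = sample(1:9, n_total, replace = TRUE),
    x = stats::runif(n_total, 1, box[1]),
    y = stats::runif(n_total, 1, box[2]),
    z = stats::runif(n_total, 1, box[3]),
    dose = dose
  )
}
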