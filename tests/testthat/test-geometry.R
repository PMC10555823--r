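test_that("tile grid reproduces the benchmarked piece-coordinate spacing", {
  grid <- tile_grid(bench_pattern(), bench_frame())
  sp <- attr(grid, "spacing_px")
  expect_identical(unname(sp["x"]), 4608L)
  expect_identical(unname(sp["y"]), 3516L)
  expect_equal(nrow(grid), 9)
  # piece coordinates anchored at the origin, non-negative integers
  expect_true(all(grid$piece_x >= 0 & grid$piece_y >= 0))
  expect_identical(grid$piece_x[grid$ix == 1 & grid$iy == 0], 4608L)
  expect_identical(grid$piece_y[grid$ix == 0 & grid$iy == 1], 3516L)
  # image shift of a tile = piece coordinate offset from centre x pixel size
  px <- 4.603e-4
  i <- which(grid$ix == 2 & grid$iy == 0)
  expect_equal(grid$shift_x_um[i], 4608 * px)
  expect_equal(grid$shift_y_um[i], -3516 * px)
  expect_true(grid$center[grid$ix == 1 & grid$iy == 1])
})

test_that("tile grid spacing formula holds over random patterns", {
  set.seed(42)
  for (i in 1:20) {
    w <- sample(50:500, 1); h <- sample(50:500, 1)
    ox <- sample(0:(w - 1), 1); oy <- sample(0:(h - 1), 1)
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    g <- tile_grid(montage_pattern(m, n, ox, oy), camera_frame(w, h, 4))
    expect_equal(nrow(g), m * n)
    sp <- attr(g, "spacing_px")
    expect_identical(unname(sp), c(w - ox, h - oy))
    if (m > 1)
      expect_true(all(diff(sort(unique(g$piece_x))) == w - ox))
  }
  # zero overlap: spacing equals frame dimensions; 1x1 is a single tile
  g0 <- tile_grid(montage_pattern(2, 2, 0, 0), camera_frame(64, 48, 2))
  expect_identical(unname(attr(g0, "spacing_px")), c(64L, 48L))
  g1 <- tile_grid(montage_pattern(1, 1, 0, 0), camera_frame(64, 48, 2))
  expect_identical(c(g1$piece_x, g1$piece_y), c(0L, 0L))
  expect_error(tile_grid(montage_pattern(2, 2, 64, 0),
                         camera_frame(64, 48, 2)), "invalid pattern")
})

test_that("grouped dose-symmetric tilt ordering is correct", {
  expect_equal(generate_tilt_angles(tilt_scheme(9, 3, group_size = 3)),
               c(0, 3, 6, 9, -3, -6, -9))
  expect_length(generate_tilt_angles(tilt_scheme(60, 3, 3)), 41)
  expect_length(generate_tilt_angles(tilt_scheme(51, 3, 3)), 35)
  expect_error(tilt_scheme(10, 3), "integer multiple")
  # bidirectional: 0 up to +max, then down the negative side
  bi <- generate_tilt_angles(tilt_scheme(9, 3, style = "bidirectional"))
  expect_equal(bi, c(0, 3, 6, 9, -3, -6, -9))
})

test_that("tilt angle lists are permutations with grouped side blocks", {
  set.seed(7)
  for (i in 1:15) {
    inc <- sample(1:5, 1)
    mx <- inc * sample(3:20, 1)
    g <- sample(1:4, 1)
    ang <- generate_tilt_angles(tilt_scheme(mx, inc, g))
    nominal <- seq(-mx, mx, by = inc)
    expect_equal(sort(ang), sort(nominal))
    expect_equal(anyDuplicated(ang), 0)
    # within each same-sign block, |angle| is non-decreasing
    side <- sign(ang[-1])
    blocks <- split(abs(ang[-1]), cumsum(c(1, diff(side) != 0)))
    for (b in blocks) expect_true(all(diff(b) >= 0))
  }
})

test_that("tilt projection and compensation cancel exactly", {
  expect_equal(project_to_image(stage_point(0, 1), 0)[["y"]], 1)
  expect_equal(project_to_image(stage_point(0, 1), 60)[["y"]], 0.5)
  expect_equal(project_to_image(stage_point(2, 0), 57)[["y"]], 0)
  expect_equal(compensation_shift(stage_point(0, 2), 0)[["y"]], 0)
  # roi y = 2 um at 60 deg: the 1 um foreshortening drift is cancelled
  sh <- compensation_shift(stage_point(0, 2), 60)
  expect_equal(2 + sh[["y"]], project_to_image(stage_point(0, 2), 60)[["y"]])
  set.seed(11)
  for (i in 1:50) {
    roi <- stage_point(stats::runif(1, -5, 5), stats::runif(1, -5, 5))
    a <- stats::runif(1, -89, 89)
    resid <- (roi[["y"]] + compensation_shift(roi, a)[["y"]]) -
      project_to_image(roi, a)[["y"]]
    expect_lt(abs(resid), 1e-9)
  }
})

test_that("beam footprint elongates as 1/cos(alpha)", {
  b <- beam_illumination(3.15)
  f0 <- footprint_at_tilt(b, 0)
  expect_equal(unname(f0), c(1.575, 1.575))
  f60 <- footprint_at_tilt(b, 60)
  expect_equal(f60[["semi_y_um"]], 2 * 1.575)
  f45 <- footprint_at_tilt(b, 45)
  area_ratio <- f45[["semi_y_um"]] / f45[["semi_x_um"]]
  expect_equal(area_ratio, sqrt(2))
  expect_error(footprint_at_tilt(b, 90), "< 90")
})

test_that("usable field of view excludes the fringe band in x only", {
  fr <- bench_frame()
  full <- usable_fov(fr, beam_illumination(3.15, fringe_fraction_x = 0))
  expect_identical(full$xmin, 0L)
  expect_identical(full$xmax, 5760L)
  f4 <- usable_fov(fr, beam_illumination(3.15, 0.04))
  expect_identical(f4$excluded_px_per_side, 230L)  # floor(0.04 * 5760)
  expect_identical(f4$ymin, 0L)
  expect_identical(f4$ymax, 4092L)
  tiny <- usable_fov(camera_frame(100, 80, 4), beam_illumination(1, 0.04))
  expect_identical(tiny$excluded_px_per_side, 4L)
})

test_that("focus/tracking sits on the tilt axis clear of every beam", {
  fr <- bench_frame(); pat <- bench_pattern()
  p <- focus_tracking_position(pat, fr, 0.8)
  grid <- tile_grid(pat, fr)
  fov <- frame_fov_um(fr)
  edge <- max(grid$shift_x_um) + fov[["x"]] / 2
  expect_equal(p[["x"]], edge + 1.3)
  expect_equal(p[["y"]], 0)
  p0 <- focus_tracking_position(pat, fr, 0)
  expect_equal(p0[["x"]], edge + 0.5)
  # never intersects any tile's illuminated area at 0 deg tilt
  beam_r <- bench_beam()$diameter_um / 2
  d <- sqrt((grid$shift_x_um - p[["x"]])^2 + (grid$shift_y_um - p[["y"]])^2)
  expect_true(all(d > beam_r))
})

test_that("projected y overlap between adjacent tiles grows with |alpha|", {
  # image-shift spacing is fixed while content spacing shrinks as y cos(a)
  grid <- tile_grid(bench_pattern(), bench_frame())
  dy_shift <- diff(sort(unique(grid$shift_y_um)))[1]
  alphas <- seq(0, 60, 10)
  content_spacing <- dy_shift * cospi(alphas / 180)
  overlap <- dy_shift - content_spacing  # extra shared content per pair
  expect_true(all(diff(overlap) > 0))
})

test_that("the benchmark configuration file loads", {
  cfg <- read_acquisition_config(
    system.file("extdata", "benchmark.yaml", package = "tomomontage"))
  expect_identical(cfg$frame$width_px, 5760L)
  expect_identical(cfg$pattern$n, 3L)
  expect_identical(cfg$pattern$overlap_x_px, 1152L)
  expect_identical(cfg$scheme$group_size, 3L)
  expect_equal(cfg$spiral$A_final, 1.5)
  bad <- tempfile(fileext = ".yaml")
  writeLines("camera:\n  width_px: 10", bad)
  expect_error(read_acquisition_config(bad), "missing")
})
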