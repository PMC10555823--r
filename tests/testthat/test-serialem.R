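test_that("mdoc documents round-trip and carry montage image shifts", {
  doc <- build_montage_mdoc(bench_frame(), bench_pattern(), bench_scheme(),
                            dose_per_exposure = 2)
  expect_length(doc$sections, 41 * 9)
  txt <- write_mdoc(doc)
  doc2 <- read_mdoc(text = txt)
  # write o read is the identity on the retained keys (byte stable)
  expect_identical(write_mdoc(doc2), txt)
  pc <- mdoc_piece_coordinates(doc2)
  is <- mdoc_image_shift(doc2)
  i1 <- which(pc[, "x"] == 0 & pc[, "y"] == 0 & pc[, "z"] == 0)[1]
  i3 <- which(pc[, "x"] == 4608 & pc[, "y"] == 0 & pc[, "z"] == 0)[1]
  # image-shift difference between tiles reproduces the montage spacing
  expect_equal(unname(is[i3, "x"] - is[i1, "x"]), 4608 * 4.603e-4,
               tolerance = 1e-5)
  expect_equal(mdoc_tilt_angles(doc2)[1:9], rep(0, 9))
})

test_that("mdoc parsing tolerates unknown keys and flags bad input", {
  lines <- c("PixelSpacing = 4.603", "Voltage = 300", "",
             "[ZValue = 0]", "TiltAngle = -0.005",
             "FancyNewKey = keep me verbatim")
  doc <- read_mdoc(text = lines)
  expect_identical(doc$header$Voltage, "300")
  expect_identical(doc$sections[[1]]$FancyNewKey, "keep me verbatim")
  out <- write_mdoc(doc)
  expect_true("FancyNewKey = keep me verbatim" %in% out)
  # empty document: empty section list
  empty <- read_mdoc(text = character(0))
  expect_length(empty$sections, 0)
  expect_error(read_mdoc(text = "not a key value line!"), "parse error")
  expect_error(mdoc_tilt_angles(read_mdoc(text = c("[ZValue = 0]",
                                                   "Foo = 1"))),
               "TiltAngle")
})

test_that("acquisition macros encode the plan and parse back exactly", {
  fr <- bench_frame()
  off <- spiral_offset_table(spiral_params(), bench_scheme(), fr, "adjusted")
  mac <- export_macro(fr, bench_beam(), bench_pattern(), bench_scheme(),
                      off, dialect = "4.1")
  expect_equal(sum(grepl("^TiltTo ", mac)), 41)  # one block per tilt
  expect_true(any(grepl("TrackingThresholdLowTilt 0.05", mac)))
  expect_true(any(grepl("TrackingThresholdHighTilt 0.10", mac)))
  expect_true(any(grepl("PauseAfterIterations 5", mac)))
  # round trip recovers the offset table exactly
  pm <- parse_macro(mac)
  expect_identical(pm$offsets$dx_um, off$dx_um)
  expect_identical(pm$offsets$dy_um, off$dy_um)
  expect_identical(pm$offsets$angle_deg, off$angle_deg)
  expect_identical(pm$mode, "adjusted")
  expect_identical(pm$pattern_mn, c(3L, 3L))
  # writers are deterministic
  expect_identical(export_macro(fr, bench_beam(), bench_pattern(),
                                bench_scheme(), off, dialect = "4.1"), mac)
  # zero-offset plan: every translational-shift line is zero
  z <- offsets_for_tilts(
    data.frame(dx_um = rep(0, 41), dy_um = rep(0, 41)),
    generate_tilt_angles(bench_scheme()), "adjusted")
  macz <- export_macro(fr, bench_beam(), bench_pattern(), bench_scheme(), z)
  offl <- grep("^PatternOffset ", macz, value = TRUE)
  expect_true(all(offl == "PatternOffset 0 0"))
  # the 3.8 dialect carries the per-tile multishot shift block
  mac38 <- export_macro(fr, bench_beam(), bench_pattern(), bench_scheme(),
                        off, dialect = "3.8")
  expect_true(any(grepl("^MultishotParams$", mac38)))
  expect_equal(sum(grepl("^  ShotShift ", mac38)), 9)
  expect_error(export_macro(fr, bench_beam(), bench_pattern(),
                            bench_scheme(), off, dialect = "5.0"),
               "unknown")
})

test_that("piece lists are written per tilt with cosine-scaled y", {
  fr <- bench_frame(); pat <- bench_pattern()
  angles <- generate_tilt_angles(bench_scheme())
  dir <- withr::local_tempdir()
  paths <- write_piece_lists(pat, fr, angles, dir)
  expect_length(paths, 41)
  # files ordered by tilt angle; each holds m x n integer coordinate lines
  first <- read_piece_list(paths[1])
  expect_equal(nrow(first), 9)
  expect_true(all(first[, "z"] == 0L))
  # y coordinates at -60 deg are the 0-deg ones scaled by cos(60)
  mid <- read_piece_list(paths[21])  # 0 deg
  expect_equal(sort(unique(mid[, "y"])), c(0L, 3516L, 7032L))
  expect_equal(sort(unique(first[, "y"])),
               as.integer(round(c(0, 3516, 7032) * 0.5)))
  # round trip through the reader; 1x1 pattern gives a single line
  d1 <- withr::local_tempdir()
  p1 <- write_piece_lists(montage_pattern(1, 1, 0, 0), fr, c(0), d1)
  expect_equal(read_piece_list(p1[1])[1, ], c(x = 0L, y = 0L, z = 0L))
})

test_that("mrc stacks round-trip through write and read", {
  set.seed(8)
  a <- array(stats::rnorm(24 * 16 * 3), c(24, 16, 3))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(a, path, pixel_size_A = 4.603)
  b <- read_mrc(path)
  expect_equal(dim(b), dim(a))
  expect_lt(max(abs(a - b)), 1e-6)  # float32 storage
  expect_equal(attr(b, "pixel_size_A"), 4.603, tolerance = 1e-6)
  m <- matrix(stats::runif(12), 4, 3)
  path2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, path2)
  expect_equal(dim(read_mrc(path2)), c(4, 3, 1))
})
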