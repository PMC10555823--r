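test_that("particles pick up the dose of their containing voxel", {
  bd <- bench_dose_maps()
  map <- bd$maps$static
  grid <- tile_grid(bench_pattern(), bench_frame())
  fr <- bench_frame()
  # particle in the centre tile, placed exactly at the centre of a known
  # canvas voxel (75, 75)
  px_um <- fr$pixel_size_A * 1e-4
  x75 <- 2880.5 + canvas_axis_um(bd$canvas, "x")[75] / px_um
  y75 <- 2046.5 + canvas_axis_um(bd$canvas, "y")[75] / px_um
  pt <- particle_table(
    id = 1:3, tomo = c(5, 5, 1),
    x = c(x75, 2880.5, 2880.5), y = c(y75, 100, 2046.5), z = 1)
  an <- annotate_dose(pt, map, grid, frame = fr)
  expect_false(any(an$off_canvas))
  expect_equal(an$dose[1], map[75, 75])
  # annotations match the dose map exactly at known voxels
  expect_true(all(an$dose %in% map))
  # particles in an unexposed region carry zero dose
  far <- particle_table(1, tomo = 5, x = 2880.5, y = 2046.5, z = 1)
  zero_map <- structure(matrix(0, 150, 150),
                        class = c("dose_map", "matrix"),
                        canvas = bd$canvas)
  expect_equal(annotate_dose(far, zero_map, grid, frame = fr)$dose, 0)
  # particles outside the canvas are flagged with undefined dose
  out <- particle_table(1, tomo = 9, x = 5e5, y = 2046, z = 1)
  an_out <- annotate_dose(out, zero_map, grid, frame = fr)
  expect_true(an_out$off_canvas)
  expect_true(is.na(an_out$dose))
  expect_error(annotate_dose(particle_table(1, tomo = 99, x = 1, y = 1,
                                            z = 1), map, grid, frame = fr),
               "unknown tile")
})

test_that("overdose filtering retains the benchmarked particle counts", {
  fx <- make_particle_fixture(seed = 4, n_total = 13021, n_overdosed = 3689)
  fl <- filter_overdosed(fx, overdose_rule(130))
  expect_equal(unname(fl$counts["kept"]), 9332)
  expect_equal(unname(fl$counts["removed"]), 3689)
  # partition: kept and removed cover the input exactly
  expect_equal(nrow(fl$kept) + nrow(fl$removed), nrow(fx))
  expect_setequal(c(fl$kept$id, fl$removed$id), fx$id)
  expect_true(all(fl$kept$dose < 130))
  expect_true(all(fl$removed$dose >= 130))
  expect_true(all(fl$kept$kept) && !any(fl$removed$kept))
})

test_that("filtering is idempotent and threshold-monotone", {
  fx <- make_particle_fixture(seed = 6, n_total = 500, n_overdosed = 120)
  fl <- filter_overdosed(fx)
  again <- filter_overdosed(fl$kept)
  expect_equal(nrow(again$kept), nrow(fl$kept))
  expect_equal(nrow(again$removed), 0)
  kept_n <- vapply(c(1e-9, 50, 130, 200, 1e6), function(th)
    unname(filter_overdosed(fx, overdose_rule(th))$counts["kept"]),
    numeric(1))
  expect_true(all(diff(kept_n) >= 0))  # raising never shrinks the kept set
  # extremes: threshold above the maximum keeps all, near zero removes all
  expect_equal(kept_n[5], nrow(fx))
  expect_equal(kept_n[1], sum(fx$dose < 1e-9))
  unann <- particle_table(1:2, tomo = 1, x = 1:2, y = 1:2, z = 1)
  expect_error(filter_overdosed(unann), "annotated")
})

test_that("tile-to-montage coordinate mapping round-trips", {
  pos <- data.frame(tile = c(1, 3), x = c(0, 4608), y = c(0, 0))
  pt <- particle_table(1:4, tomo = c(1, 3, 3, 1),
                       x = c(10, 10, 500.25, 99), y = c(20, 20, 30.5, 7),
                       z = 1)
  m <- map_to_montage(pt, pos)
  expect_equal(m$x, c(10, 4618, 5108.25, 99))  # tile at (0,0): identity
  expect_equal(m$y, pt$y)
  back <- map_to_montage(m, pos, invert = TRUE)
  expect_equal(back$x, pt$x)
  expect_equal(back$y, pt$y)
  expect_error(map_to_montage(particle_table(1, tomo = 7, x = 1, y = 1,
                                             z = 1), pos), "unknown tile")
})

test_that("particle tables round-trip through csv and export to dynamo", {
  fx <- make_particle_fixture(seed = 7, n_total = 50, n_overdosed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_particle_table(fx, path)
  back <- read_particle_table(path)
  expect_equal(back$dose, fx$dose)
  expect_equal(back$id, fx$id)
  dyn <- as_dynamo_table(fx)
  expect_equal(dim(dyn), c(50, 35))
  expect_equal(dyn[, 24], fx$x)
})
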