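test_that("rasterization matches the supersampled footprint oracle", {
  cv <- stage_canvas()
  plan <- data.frame(angle_deg = 0, beam_x_um = 0.3, beam_y_um = -0.2,
                     diameter_um = 4, dose = 1)
  map <- simulate_dose(plan, cv)
  frac <- supersampled_footprint(cv, 0.3, -0.2, 2, 2)
  oracle <- frac >= 0.5
  centre <- unclass(map) > 0
  agree <- mean(centre == oracle)
  expect_gte(agree, 0.995)
  mism <- which(centre != oracle)
  # all mismatches lie on the footprint boundary (partially covered voxels)
  expect_true(all(frac[mism] > 0 & frac[mism] < 1))
  expect_lt(abs(sum(centre) - sum(oracle)) / sum(oracle), 0.01)
})

test_that("dose accumulates once per beam, additively and order-free", {
  cv <- stage_canvas()
  sch <- bench_scheme()
  angles <- generate_tilt_angles(sch)
  # 41-tilt single-tile series, no offsets: centre voxel sees every beam
  plan <- data.frame(angle_deg = angles, beam_x_um = 0, beam_y_um = 0,
                     diameter_um = 3.15, dose = 2)
  map <- simulate_dose(plan, cv)
  expect_equal(map[75, 75], 41 * 2)
  # permuting the exposures yields an identical map
  set.seed(1)
  map_p <- simulate_dose(plan[sample(nrow(plan)), ], cv)
  expect_identical(unclass(map_p)[, ], unclass(map)[, ])
  # two overlapping 0-deg tiles: overlap voxel gets exactly 2x the dose
  two <- data.frame(angle_deg = 0, beam_x_um = c(-1, 1), beam_y_um = 0,
                    diameter_um = 3.15, dose = 2)
  m2 <- simulate_dose(two, cv)
  expect_equal(m2[75, 75], 4)  # centre is inside both footprints
  expect_equal(max(m2), 4)
  # dose conservation: total = sum over exposures of dose x voxel count
  xs <- canvas_axis_um(cv, "x"); ys <- canvas_axis_um(cv, "y")
  tot <- 0
  for (i in seq_len(nrow(plan))) {
    b <- plan$diameter_um[i] / 2 / cospi(plan$angle_deg[i] / 180)
    u <- (xs - plan$beam_x_um[i]) / (plan$diameter_um[i] / 2)
    v <- (ys - plan$beam_y_um[i]) / b
    tot <- tot + plan$dose[i] * sum(outer(u^2, v^2, `+`) <= 1)
  }
  expect_identical(sum(map), tot)
  # footprint entirely off canvas: warning, no contribution
  off <- data.frame(angle_deg = 0, beam_x_um = 50, beam_y_um = 0,
                    diameter_um = 3.15, dose = 2)
  expect_warning(m_off <- simulate_dose(off, cv), "off canvas")
  expect_equal(sum(m_off), 0)
})

test_that("tilted footprints dose ~1/cos(alpha) times the 0-deg voxels", {
  cv <- stage_canvas()
  n0 <- sum(simulate_dose(data.frame(angle_deg = 0, beam_x_um = 0,
                                     beam_y_um = 0, diameter_um = 3.15,
                                     dose = 1), cv) > 0)
  for (a in c(30, 45, 60)) {
    na <- sum(simulate_dose(data.frame(angle_deg = a, beam_x_um = 0,
                                       beam_y_um = 0, diameter_um = 3.15,
                                       dose = 1), cv) > 0)
    expect_equal(na / n0, 1 / cospi(a / 180), tolerance = 0.03)
  }
})

test_that("region statistics behave on uniform and montage maps", {
  bd <- bench_dose_maps()
  reg <- bd$regions
  # uniform map: every region reports identical statistics
  uni <- structure(matrix(7, 150, 150), class = c("dose_map", "matrix"),
                   canvas = bd$canvas)
  su <- dose_stats(uni, reg)
  expect_true(all(su$mean == 7 & su$min == 7 & su$max == 7 & su$sd == 0))
  # overlap bands accumulate at least the interior mean on a regular array
  ss <- dose_stats(bd$maps$static, reg)
  expect_gte(ss$mean[ss$region == "overlap_x"],
             ss$mean[ss$region == "interior"])
  expect_gte(ss$mean[ss$region == "overlap_y"],
             ss$mean[ss$region == "interior"])
  # single exposure: interior max equals the exposure dose
  one <- simulate_dose(data.frame(angle_deg = 0, beam_x_um = 0,
                                  beam_y_um = 0, diameter_um = 3.15,
                                  dose = 1.42), bd$canvas)
  so <- dose_stats(one, reg)
  expect_equal(so$max[so$region == "interior"], 1.42)
  expect_error(dose_stats(uni, list(empty = matrix(FALSE, 150, 150))),
               "empty region")
})

test_that("spiral shifts redistribute overlap dose as described", {
  bd <- bench_dose_maps()
  reg <- bd$regions
  st <- lapply(bd$maps, dose_stats, regions = reg)
  band_mean <- function(s, b) s$mean[s$region == b]
  # adjusted spiral: more uniform - strictly lower overlap-band means and
  # strictly lower spread over the covered region than the no-shift plan
  expect_lt(band_mean(st$adjusted, "overlap_x"),
            band_mean(st$static, "overlap_x"))
  expect_lt(band_mean(st$adjusted, "overlap_y"),
            band_mean(st$static, "overlap_y"))
  expect_lt(st$adjusted$sd[st$adjusted$region == "roi"],
            st$static$sd[st$static$region == "roi"])
  # unadjusted spiral: lower, more restricted overlap-zone accumulation -
  # the overlap-zone maximum drops strictly below the no-shift plan's
  overlap <- reg$overlap_x | reg$overlap_y
  expect_lt(max(bd$maps$unadjusted[overlap]), max(bd$maps$static[overlap]))
})

test_that("overdose masks threshold the accumulated dose", {
  bd <- bench_dose_maps()
  m <- bd$maps$static
  expect_false(any(overdose_mask(m, max(m) + 1)))
  expect_identical(overdose_mask(m, 1e-12), unclass(m)[, ] > 0)
  # constructed map with a known overdosed voxel count
  k <- 37
  fake <- structure(matrix(0, 150, 150), class = c("dose_map", "matrix"),
                    canvas = bd$canvas)
  fake[seq_len(k)] <- 130 + seq_len(k)
  fake[k + seq_len(10)] <- 129.9
  expect_equal(sum(overdose_mask(fake, 130)), k)
})

test_that("dose maps export losslessly to full-grid csv", {
  bd <- bench_dose_maps()
  path <- withr::local_tempfile(fileext = ".csv")
  export_dose_csv(bd$maps$static, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 150 * 150)  # 22,500 voxel rows
  back <- read_dose_csv(path, bd$canvas)
  expect_identical(unclass(back)[, ], unclass(bd$maps$static)[, ])
  # an all-zero map still exports the full grid
  zero <- structure(matrix(0, 4, 3), class = c("dose_map", "matrix"),
                    canvas = stage_canvas(4, 3, 2, c(1, 1, 0.2)))
  zpath <- withr::local_tempfile(fileext = ".csv")
  export_dose_csv(zero, zpath)
  expect_equal(nrow(utils::read.csv(zpath)), 4 * 3 * 2)
})
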