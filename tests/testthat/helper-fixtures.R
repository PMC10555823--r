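# Shared fixtures, built once per test run.

.shared <- new.env(parent = emptyenv())

bench_frame <- function() camera_frame(5760, 4092, 4.603)
bench_beam <- function() beam_illumination(3.15)
bench_pattern <- function() montage_pattern(3, 3, 1152, 576)
bench_scheme <- function() tilt_scheme(60, 3, group_size = 3)

# desk-scale 3x3 x 21-tilt dataset with the default (adjusted) spiral
desk_dataset <- function() {
  if (is.null(.shared$ds)) .shared$ds <- make_montage_dataset(seed = 5)
  .shared$ds
}

# same geometry without spiral offsets (clean drift baseline)
desk_dataset_static <- function() {
  if (is.null(.shared$ds0))
    .shared$ds0 <- make_montage_dataset(seed = 5, spiral = NULL)
  .shared$ds0
}

desk_two_paths <- function() {
  if (is.null(.shared$tp)) .shared$tp <- run_two_paths(desk_dataset())
  .shared$tp
}

# benchmark-geometry dose maps: static, adjusted spiral, unadjusted spiral
bench_dose_maps <- function() {
  if (is.null(.shared$maps)) {
    fr <- bench_frame(); bm <- bench_beam()
    pat <- bench_pattern(); sch <- bench_scheme()
    cv <- stage_canvas()
    plans <- list(
      static = build_exposure_plan(fr, bm, pat, sch, NULL,
                                   dose_per_exposure = 2),
      adjusted = build_exposure_plan(
        fr, bm, pat, sch, spiral_offset_table(spiral_params(), sch, fr,
                                              "adjusted"),
        dose_per_exposure = 2),
      unadjusted = build_exposure_plan(
        fr, bm, pat, sch, spiral_offset_table(spiral_params(), sch, fr,
                                              "unadjusted"),
        dose_per_exposure = 2)
    )
    .shared$maps <- list(
      maps = lapply(plans, simulate_dose, canvas = cv),
      plans = plans,
      regions = montage_regions(pat, fr, cv),
      canvas = cv
    )
  }
  .shared$maps
}

# 64x supersampled inside-ellipse oracle for one exposure footprint
supersampled_footprint <- function(canvas, cx, cy, a, b, nsub = 8) {
  xs <- canvas_axis_um(canvas, "x")
  ys <- canvas_axis_um(canvas, "y")
  sub <- (seq_len(nsub) - (nsub + 1) / 2) / nsub
  frac <- matrix(0, canvas$nx, canvas$ny)
  for (dx in sub) {
    for (dy in sub) {
      u <- (xs + dx * canvas$voxel_um[1] - cx) / a
      v <- (ys + dy * canvas$voxel_um[2] - cy) / b
      frac <- frac + (outer(u^2, v^2, `+`) <= 1)
    }
  }
  frac / nsub^2
}
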