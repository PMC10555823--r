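# Archimedean-spiral translational offsets for dose spreading.
#
# The whole montage pattern is displaced at each tilt along an Archimedean
# spiral designed at 0 deg.  `period` exposures share one spiral sample, the
# sample index s advances by 1 every `period` tilts (s_0 = 0, the origin);
# sample s sits at radius A_final * s / turns and angle
# 2*pi * revolutions * s / turns.

#' Spiral trajectory parameters
#'
#' Defaults reproduce the benchmarked acquisition setting
#' (A_final = 1.5, period = 3, turns = 50, revolutions = 15).
#'
#' @param A_final Terminal spiral amplitude, micrometres.
#' @param period Exposures per spiral step (echoes the grouped tilt scheme).
#' @param turns Number of spiral samples spanning the amplitude.
#' @param revolutions Total angular revolutions across the samples.
#' @return An object of class `spiral_params`.
#' @export
spiral_params <- function(A_final = 1.5, period = 3, turns = 50,
                          revolutions = 15) {
  stopifnot(A_final >= 0, period >= 1, period == as.integer(period),
            turns >= 1, revolutions >= 0)
  structure(list(A_final = A_final, period = as.integer(period),
                 turns = turns, revolutions = revolutions),
            class = "spiral_params")
}

#' Archimedean spiral design points at 0 deg tilt
#'
#' @param params A [spiral_params()].
#' @param n_tilts Number of exposures (tilts) to generate points for.
#' @return Data frame with `k` (0-based tilt index), `s` (spiral sample
#'   index), `dx_um`, `dy_um`, `r_um`.  The first point is the origin and
#'   the radius is non-decreasing in `k`.
#' @export
archimedean_points <- function(params, n_tilts) {
  stopifnot(inherits(params, "spiral_params"), n_tilts >= 1)
  k <- seq_len(n_tilts) - 1L
  s <- k %/% params$period
  r <- params$A_final * s / params$turns
  phi <- 2 * pi * params$revolutions * s / params$turns
  data.frame(k = k, s = s,
             dx_um = r * cos(phi), dy_um = r * sin(phi), r_um = r)
}

#' Clamp spiral offsets to a fraction of the field of view
#'
#' Restricting the largest translational offset to 30 % or less of the
#' long-axis FOV keeps the region of interest inside every tile across the
#' full tilt range.  If any design radius exceeds the clamp, all points are
#' scaled down proportionally.
#'
#' @param points Data frame from [archimedean_points()] (or any with
#'   `dx_um`, `dy_um`).
#' @param frame A [camera_frame()].
#' @param fraction Fraction of the long-axis FOV, in `(0, 1]`; default 0.30.
#' @return List with `points` (clamped), `max_offset_um` (the clamp,
#'   fraction x long-axis FOV) and `scaled` (logical, whether scaling was
#'   applied).
#' @examples
#' fr <- camera_frame(5760, 4092, 4.603)
#' clamp_offsets(archimedean_points(spiral_params(), 41), fr)$max_offset_um
#' # 0.795 um, the ~0.8 um offset budget of the benchmarked setting
#' @export
clamp_offsets <- function(points, frame, fraction = 0.30) {
  stopifnot(inherits(frame, "camera_frame"), fraction > 0, fraction <= 1)
  clamp <- fraction * frame_fov_um(frame)[["x"]]
  r <- sqrt(points$dx_um^2 + points$dy_um^2)
  scaled <- any(r > clamp)
  if (scaled) {
    f <- clamp / max(r)
    points$dx_um <- points$dx_um * f
    points$dy_um <- points$dy_um * f
    if ("r_um" %in% names(points)) points$r_um <- points$r_um * f
  }
  list(points = points, max_offset_um = clamp, scaled = scaled)
}

#' Per-tilt offset table in adjusted or unadjusted mode
#'
#' The design points are the beam-frame (image-plane) displacements at 0 deg.
#' In `unadjusted` mode the beam-frame offset equals the design point at
#' every tilt, so on the tilted stage the trajectory stretches along y by
#' 1/cos(alpha).  In `adjusted` mode ("Adjust Shifts by Tilt Angle") the
#' beam-frame y offset is scaled by cos(alpha) so that the stage-plane
#' trajectory is identical at every tilt to the 0 deg design.  x offsets are
#' identical in both modes (tilt axis).
#'
#' @param points Design points (`dx_um`, `dy_um`), one per tilt in
#'   acquisition order.
#' @param angles Tilt angles in acquisition order, same length as `points`.
#' @param mode `"adjusted"` or `"unadjusted"`.
#' @param max_offset_um Optional clamp actually applied (recorded as an
#'   attribute; offsets are assumed already clamped).
#' @return An `offset_table` data frame: `tilt_index` (0-based), `angle_deg`,
#'   `dx_um`, `dy_um` (beam-frame), with attributes `mode` and
#'   `max_offset_um`.
#' @export
offsets_for_tilts <- function(points, angles,
                              mode = c("adjusted", "unadjusted"),
                              max_offset_um = NA_real_) {
  if (length(mode) == 1 && !mode %in% c("adjusted", "unadjusted"))
    stop("unknown offset mode: ", mode)
  mode <- match.arg(mode)
  stopifnot(nrow(points) == length(angles))
  dy <- if (mode == "adjusted") {
    points$dy_um * cospi(angles / 180)
  } else {
    points$dy_um
  }
  tab <- data.frame(tilt_index = seq_along(angles) - 1L,
                    angle_deg = angles,
                    dx_um = points$dx_um, dy_um = dy)
  structure(tab, mode = mode, max_offset_um = max_offset_um,
            class = c("offset_table", "data.frame"))
}

#' Stage-plane offsets implied by an offset table
#'
#' A beam-frame (image-plane) displacement dy maps onto the tilted stage as
#' dy / cos(alpha); x is unchanged.
#'
#' @param table An `offset_table` from [offsets_for_tilts()].
#' @return Data frame `tilt_index`, `angle_deg`, `dx_um`, `dy_um` in
#'   stage-plane micrometres.
#' @export
stage_plane_offsets <- function(table) {
  data.frame(tilt_index = table$tilt_index, angle_deg = table$angle_deg,
             dx_um = table$dx_um,
             dy_um = table$dy_um / cospi(table$angle_deg / 180))
}

#' Build a clamped spiral offset table for a tilt scheme
#'
#' Convenience wrapper: design points from [archimedean_points()], clamped by
#' [clamp_offsets()], expanded per tilt by [offsets_for_tilts()].
#'
#' @param params A [spiral_params()].
#' @param scheme A [tilt_scheme()].
#' @param frame A [camera_frame()].
#' @param mode Offset mode, see [offsets_for_tilts()].
#' @param fraction FOV fraction for the clamp.
#' @return An `offset_table`.
#' @export
spiral_offset_table <- function(params, scheme, frame,
                                mode = c("adjusted", "unadjusted"),
                                fraction = 0.30) {
  mode <- match.arg(mode)
  angles <- generate_tilt_angles(scheme)
  pts <- archimedean_points(params, length(angles))
  cl <- clamp_offsets(pts, frame, fraction)
  offsets_for_tilts(cl$points, angles, mode, max_offset_um = cl$max_offset_um)
}

#' Write / read an offset table as comma-separated text
#'
#' Columns: `tilt_index, angle_deg, dx_um, dy_um, mode`.  Numeric values are
#' written with full precision so the round trip is exact.
#'
#' @param table An `offset_table`.
#' @param path File path.
#' @return `write_offset_table` returns `path` invisibly; `read_offset_table`
#'   returns an `offset_table`.
#' @export
write_offset_table <- function(table, path) {
  out <- data.frame(tilt_index = table$tilt_index,
                    angle_deg = sprintf("%.17g", table$angle_deg),
                    dx_um = sprintf("%.17g", table$dx_um),
                    dy_um = sprintf("%.17g", table$dy_um),
                    mode = attr(table, "mode"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_offset_table
#' @export
read_offset_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  mode <- unique(tab$mode)
  stopifnot(length(mode) == 1)
  structure(
    data.frame(tilt_index = as.integer(tab$tilt_index),
               angle_deg = as.numeric(tab$angle_deg),
               dx_um = as.numeric(tab$dx_um), dy_um = as.numeric(tab$dy_um)),
    mode = mode, max_offset_um = NA_real_,
    class = c("offset_table", "data.frame")
  )
}
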