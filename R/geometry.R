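# Static acquisition geometry: camera frame, beam, tile grids, tilt schemes,
# tilt projections, focus/tracking placement.
#
# Conventions (used throughout the package):
#   * right-handed stage frame; the tilt axis is +x, the beam travels along z;
#   * stage and image-plane coordinates are in micrometres, pixel sampling in
#     Angstrom per pixel (1 um = 1e4 A);
#   * image pixels are 0-based with the origin at the lower-left frame corner;
#   * piece coordinates are unbinned frame pixels, z slot = tilt index.

#' Camera frame description
#'
#' @param width_px Frame width in pixels (long axis, x).
#' @param height_px Frame height in pixels (short axis, y).
#' @param pixel_size_A Sampling at the specimen, in Angstrom per pixel.
#'
#' @return An object of class `camera_frame`.
#' @examples
#' k3 <- camera_frame(5760, 4092, 4.603)
#' frame_fov_um(k3) # about 2.65 x 1.88 um
#' @export
camera_frame <- function(width_px, height_px, pixel_size_A) {
  stopifnot(
    is.numeric(width_px), length(width_px) == 1, width_px > 0,
    width_px == as.integer(width_px),
    is.numeric(height_px), length(height_px) == 1, height_px > 0,
    height_px == as.integer(height_px),
    is.numeric(pixel_size_A), length(pixel_size_A) == 1, pixel_size_A > 0
  )
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_A = pixel_size_A),
    class = "camera_frame"
  )
}

#' Physical field of view of a camera frame
#'
#' @param frame A [camera_frame()].
#' @return Named numeric vector `c(x, y)` in micrometres.
#' @export
frame_fov_um <- function(frame) {
  stopifnot(inherits(frame, "camera_frame"))
  c(x = frame$width_px * frame$pixel_size_A * 1e-4,
    y = frame$height_px * frame$pixel_size_A * 1e-4)
}

#' @export
print.camera_frame <- function(x, ...) {
  fov <- frame_fov_um(x)
  cat(sprintf("camera frame: %d x %d px @ %.4g A/px (%.3f x %.3f um)\n",
              x$width_px, x$height_px, x$pixel_size_A, fov["x"], fov["y"]))
  invisible(x)
}

#' Beam illumination description
#'
#' The fringe fraction is the portion of the frame's x dimension, measured
#' inward from each side where the beam edge crosses the frame, that is
#' treated as impacted by Fresnel fringes from the beam-defining aperture.
#' The default 0.04 is the upper bound of the 3.5--4 % band measured on a
#' standard (non fringe-free) 300 kV instrument.
#'
#' @param diameter_um Illuminated-area diameter at the specimen, micrometres.
#' @param fringe_fraction_x Fringe-impacted fraction of x per side, in
#'   `[0, 0.5)`.
#' @return An object of class `beam_illumination`.
#' @export
beam_illumination <- function(diameter_um, fringe_fraction_x = 0.04) {
  stopifnot(
    is.numeric(diameter_um), length(diameter_um) == 1, diameter_um > 0,
    is.numeric(fringe_fraction_x), length(fringe_fraction_x) == 1,
    fringe_fraction_x >= 0, fringe_fraction_x < 0.5
  )
  structure(
    list(diameter_um = diameter_um, fringe_fraction_x = fringe_fraction_x),
    class = "beam_illumination"
  )
}

#' Montage tile pattern
#'
#' Overlaps are stored in pixels; [overlap_px()] converts fractional overlaps.
#' Tiles are traversed row-major from the (-x, -y) corner; the centre tile is
#' at column `floor(m/2)`, row `floor(n/2)` (0-based).
#'
#' @param m Tiles along x.
#' @param n Tiles along y.
#' @param overlap_x_px Pixel overlap between x-adjacent tiles.
#' @param overlap_y_px Pixel overlap between y-adjacent tiles.
#' @return An object of class `montage_pattern`.
#' @export
montage_pattern <- function(m, n, overlap_x_px, overlap_y_px) {
  stopifnot(
    is.numeric(m), length(m) == 1, m >= 1, m == as.integer(m),
    is.numeric(n), length(n) == 1, n >= 1, n == as.integer(n),
    is.numeric(overlap_x_px), length(overlap_x_px) == 1, overlap_x_px >= 0,
    overlap_x_px == as.integer(overlap_x_px),
    is.numeric(overlap_y_px), length(overlap_y_px) == 1, overlap_y_px >= 0,
    overlap_y_px == as.integer(overlap_y_px)
  )
  structure(
    list(m = as.integer(m), n = as.integer(n),
         overlap_x_px = as.integer(overlap_x_px),
         overlap_y_px = as.integer(overlap_y_px)),
    class = "montage_pattern"
  )
}

#' Convert fractional tile overlap to pixels
#'
#' @param frame A [camera_frame()].
#' @param fraction_x,fraction_y Overlap fractions of the frame dimensions.
#' @return Named integer vector `c(x, y)` of pixel overlaps (floored).
#' @export
overlap_px <- function(frame, fraction_x, fraction_y) {
  stopifnot(inherits(frame, "camera_frame"),
            fraction_x >= 0, fraction_x < 1, fraction_y >= 0, fraction_y < 1)
  c(x = as.integer(floor(fraction_x * frame$width_px)),
    y = as.integer(floor(fraction_y * frame$height_px)))
}

#' Tilt scheme
#'
#' @param max_angle_deg Positive tilt limit; the range is symmetric, +/- max.
#' @param increment_deg Tilt step in degrees; must divide `max_angle_deg`.
#' @param group_size Tilts acquired per side before switching sides in the
#'   grouped dose-symmetric ordering (the original Hagen scheme is group 1).
#' @param style `"dose-symmetric"` or `"bidirectional"`.
#' @return An object of class `tilt_scheme`.
#' @export
tilt_scheme <- function(max_angle_deg, increment_deg, group_size = 1,
                        style = c("dose-symmetric", "bidirectional")) {
  style <- match.arg(style)
  stopifnot(
    is.numeric(max_angle_deg), length(max_angle_deg) == 1, max_angle_deg > 0,
    is.numeric(increment_deg), length(increment_deg) == 1, increment_deg > 0,
    increment_deg <= max_angle_deg,
    is.numeric(group_size), length(group_size) == 1, group_size >= 1
  )
  steps <- max_angle_deg / increment_deg
  if (abs(steps - round(steps)) > 1e-9)
    stop("max_angle_deg must be an integer multiple of increment_deg")
  structure(
    list(max_angle_deg = max_angle_deg, increment_deg = increment_deg,
         group_size = as.integer(group_size), style = style),
    class = "tilt_scheme"
  )
}

#' Stage-plane point
#'
#' @param x_um,y_um,z_um Coordinates in micrometres (tilt axis x, beam z).
#' @return Named numeric vector of class `stage_point`.
#' @export
stage_point <- function(x_um, y_um, z_um = 0) {
  stopifnot(is.finite(x_um), is.finite(y_um), is.finite(z_um))
  structure(c(x = x_um, y = y_um, z = z_um), class = "stage_point")
}

#' Tile grid: piece coordinates and image-shift vectors
#'
#' Lays out an m x n beam-image-shift tile pattern on a camera frame.  The
#' spacing between x-adjacent tiles is `width_px - overlap_x_px` and between
#' y-adjacent tiles `height_px - overlap_y_px`; piece coordinates are
#' non-negative pixels anchored at (0, 0, 0), and each tile's image-shift
#' vector (micrometres) is its piece coordinate times the pixel size,
#' relative to the pattern's centre tile.
#'
#' @param pattern A [montage_pattern()].
#' @param frame A [camera_frame()].
#' @return A data frame with one row per tile: `tile` (1-based, row-major
#'   from the (-x,-y) corner), `ix`, `iy` (0-based column/row), `piece_x`,
#'   `piece_y` (pixels), `shift_x_um`, `shift_y_um`, and a logical `center`.
#'   Attributes `spacing_px` (c(x, y)) and `center_tile` are attached.
#' @examples
#' fr <- camera_frame(5760, 4092, 4.603)
#' tg <- tile_grid(montage_pattern(3, 3, 1152, 576), fr)
#' attr(tg, "spacing_px") # 4608, 3516
#' @export
tile_grid <- function(pattern, frame) {
  stopifnot(inherits(pattern, "montage_pattern"),
            inherits(frame, "camera_frame"))
  if (pattern$overlap_x_px >= frame$width_px ||
      pattern$overlap_y_px >= frame$height_px)
    stop("invalid pattern: overlap must be smaller than the frame dimension")
  sx <- frame$width_px - pattern$overlap_x_px
  sy <- frame$height_px - pattern$overlap_y_px
  ix <- rep(seq_len(pattern$m) - 1L, times = pattern$n)
  iy <- rep(seq_len(pattern$n) - 1L, each = pattern$m)
  cx <- pattern$m %/% 2L
  cy <- pattern$n %/% 2L
  px_um <- frame$pixel_size_A * 1e-4
  grid <- data.frame(
    tile = seq_along(ix),
    ix = ix, iy = iy,
    piece_x = ix * sx, piece_y = iy * sy,
    shift_x_um = (ix - cx) * sx * px_um,
    shift_y_um = (iy - cy) * sy * px_um,
    center = ix == cx & iy == cy
  )
  attr(grid, "spacing_px") <- c(x = sx, y = sy)
  attr(grid, "center_tile") <- which(grid$center)
  grid
}

#' Tilt-angle list in acquisition order
#'
#' Dose-symmetric style starts at 0 deg and alternates sides of the tilt axis
#' in blocks of `group_size`, taking angles of non-decreasing magnitude so
#' that the low-tilt, high-value exposures accumulate the least dose.
#' Bidirectional style runs 0 to +max, then -increment down to -max.
#'
#' @param scheme A [tilt_scheme()].
#' @return Numeric vector of angles (degrees), each nominal angle once;
#'   length `2 * max/increment + 1`.
#' @examples
#' generate_tilt_angles(tilt_scheme(9, 3, group_size = 3))
#' # 0 3 6 9 -3 -6 -9
#' @export
generate_tilt_angles <- function(scheme) {
  stopifnot(inherits(scheme, "tilt_scheme"))
  k <- as.integer(round(scheme$max_angle_deg / scheme$increment_deg))
  pos <- seq_len(k) * scheme$increment_deg
  if (scheme$style == "bidirectional")
    return(c(0, pos, -pos))
  g <- scheme$group_size
  angles <- 0
  ip <- 0L  # positive angles consumed
  im <- 0L  # negative angles consumed
  side_pos <- TRUE
  while (ip < k || im < k) {
    if (side_pos && ip < k) {
      take <- min(g, k - ip)
      angles <- c(angles, pos[ip + seq_len(take)])
      ip <- ip + take
    } else if (!side_pos && im < k) {
      take <- min(g, k - im)
      angles <- c(angles, -pos[im + seq_len(take)])
      im <- im + take
    }
    side_pos <- !side_pos
  }
  angles
}

#' Project a stage point onto the image plane at a tilt angle
#'
#' Tilting about the x axis foreshortens the y coordinate: a feature at stage
#' y appears at image y * cos(alpha); x is unchanged (tilt axis).
#'
#' @param p A [stage_point()] (or numeric `c(x, y)`).
#' @param alpha_deg Tilt angle in degrees, `|alpha| < 90`.
#' @return Named numeric `c(x, y)` image-plane position in micrometres.
#' @export
project_to_image <- function(p, alpha_deg) {
  stopifnot(abs(alpha_deg) < 90)
  c(x = unname(p[1]), y = unname(p[2]) * cospi(alpha_deg / 180))
}

#' Beam-image shift compensating off-axis ROI drift
#'
#' An off-axis region of interest drifts toward the tilt axis as y*cos(alpha)
#' while its tile centre stays at the fixed image shift chosen at 0 deg.  The
#' returned shift, added to the tile's image-shift vector, re-centres the
#' projected ROI in its tile exactly (noiseless geometry).
#'
#' @param roi A [stage_point()] for the tile's region of interest.
#' @param alpha_deg Tilt angle, `|alpha| < 90`.
#' @return Named numeric `c(x, y)` shift in micrometres.
#' @export
compensation_shift <- function(roi, alpha_deg) {
  stopifnot(abs(alpha_deg) < 90)
  c(x = 0, y = unname(roi[2]) * (cospi(alpha_deg / 180) - 1))
}

#' Stage-plane beam footprint at a tilt angle
#'
#' A circular illuminated area of radius r elongates on the tilted stage into
#' an ellipse with semi-axis r along x (tilt axis) and r / cos(alpha) along y,
#' so the illuminated area grows by 1 / cos(alpha).
#'
#' @param beam A [beam_illumination()].
#' @param alpha_deg Tilt angle, `|alpha| < 90`.
#' @return Named numeric `c(semi_x_um, semi_y_um)`.
#' @export
footprint_at_tilt <- function(beam, alpha_deg) {
  stopifnot(inherits(beam, "beam_illumination"))
  if (abs(alpha_deg) >= 90) stop("|alpha_deg| must be < 90")
  r <- beam$diameter_um / 2
  c(semi_x_um = r, semi_y_um = r / cospi(alpha_deg / 180))
}

#' Fringe-free usable field of view
#'
#' Excludes `floor(fringe_fraction_x * width_px)` pixels from each x side of
#' the frame, where the beam edge intersects the frame and Fresnel fringes
#' contaminate the image; y is unaffected (the measured y impact is below
#' detectability for the benchmarked beam).
#'
#' @param frame A [camera_frame()].
#' @param beam A [beam_illumination()].
#' @return List with `xmin`, `xmax`, `ymin`, `ymax` (0-based pixel bounds,
#'   `[xmin, xmax)`), and `excluded_px_per_side`.
#' @export
usable_fov <- function(frame, beam) {
  stopifnot(inherits(frame, "camera_frame"),
            inherits(beam, "beam_illumination"))
  excl <- as.integer(floor(beam$fringe_fraction_x * frame$width_px))
  list(xmin = excl, xmax = frame$width_px - excl,
       ymin = 0L, ymax = frame$height_px,
       excluded_px_per_side = excl)
}

#' Focus and tracking position for a montage pattern
#'
#' Autofocus/tracking is placed on the tilt axis through the pattern centre,
#' 0.5 um plus the maximum translational offset beyond the edge of the
#' montage tile pattern, so the measuring beam never touches the region of
#' interest at any applied spiral offset.
#'
#' @param pattern A [montage_pattern()].
#' @param frame A [camera_frame()].
#' @param max_offset_um Largest translational offset the plan applies (>= 0).
#' @return A [stage_point()] relative to the pattern centre.
#' @export
focus_tracking_position <- function(pattern, frame, max_offset_um) {
  stopifnot(max_offset_um >= 0)
  grid <- tile_grid(pattern, frame)
  fov <- frame_fov_um(frame)
  # half-extent of the tile pattern along x, frame-based
  half_x <- max(grid$shift_x_um) + fov["x"] / 2
  stage_point(unname(half_x) + 0.5 + max_offset_um, 0)
}
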