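# Dose-based curation of sub-tomogram particle tables: annotate particles
# with accumulated dose from a simulated dose map, remove overdosed ones,
# and map tile-frame coordinates into the stitched montage frame.

#' Particle table
#'
#' @param id Unique particle identifiers.
#' @param tomo Source tomogram / tile id per particle.
#' @param x,y,z Particle coordinates in source-volume voxels.
#' @param dose Accumulated dose, electrons per square Angstrom (NA until
#'   annotated).
#' @param score Optional correlation score.
#' @return A `particle_table` data frame with a logical `kept` column
#'   (all `TRUE` before filtering).
#' @export
particle_table <- function(id, tomo, x, y, z, dose = NA_real_,
                           score = NA_real_) {
  stopifnot(!anyDuplicated(id))
  structure(
    data.frame(id = id, tomo = tomo, x = x, y = y, z = z, dose = dose,
               score = score, kept = TRUE),
    class = c("particle_table", "data.frame")
  )
}

#' Overdose rule
#'
#' The benchmark threshold is 130 electrons per square Angstrom, at least
#' twofold above the regular dose tolerance of the specimen.
#'
#' @param threshold_e_per_A2 Dose at or above which a particle is removed.
#' @return Object of class `overdose_rule`.
#' @export
overdose_rule <- function(threshold_e_per_A2 = 130) {
  stopifnot(threshold_e_per_A2 > 0)
  structure(list(threshold_e_per_A2 = threshold_e_per_A2),
            class = "overdose_rule")
}

#' Annotate particles with accumulated dose from a dose map
#'
#' Each particle's (x, y) tile coordinate is mapped to the stage plane via
#' its tile's geometry and looked up in the nearest dose-map voxel (no
#' interpolation; particle extents are ignored, as particles are small
#' relative to overlap bands).  Particles falling outside the canvas are
#' flagged with `off_canvas = TRUE` and keep an undefined dose.
#'
#' @param particles A [particle_table()]; `tomo` must index rows of
#'   `tile_geometry`.
#' @param dose_map A `dose_map` from [simulate_dose()].
#' @param tile_geometry Data frame with per-tile `tile`, `center_x_um`,
#'   `center_y_um` (stage position of the tile centre) and `pixel_size_A`
#'   of the particle coordinates; a [tile_grid()] result is accepted
#'   (columns `tile`, `shift_x_um`, `shift_y_um`) together with
#'   `pixel_size_A` supplied via the `frame` argument.
#' @param frame Optional [camera_frame()] supplying the pixel size and
#'   frame centre when `tile_geometry` is a [tile_grid()] result.
#' @return The particle table with `dose` filled and `off_canvas` added.
#' @export
annotate_dose <- function(particles, dose_map, tile_geometry, frame = NULL) {
  canvas <- attr(dose_map, "canvas")
  stopifnot(!is.null(canvas))
  if (!is.null(frame) && "shift_x_um" %in% names(tile_geometry)) {
    tile_geometry <- data.frame(
      tile = tile_geometry$tile,
      center_x_um = tile_geometry$shift_x_um,
      center_y_um = tile_geometry$shift_y_um,
      pixel_size_A = frame$pixel_size_A,
      width_px = frame$width_px, height_px = frame$height_px
    )
  }
  idx <- match(particles$tomo, tile_geometry$tile)
  if (any(is.na(idx))) stop("particles reference unknown tile ids")
  px_um <- tile_geometry$pixel_size_A[idx] * 1e-4
  # tile-frame voxel -> stage um (frame centred on the tile's stage centre)
  sx <- tile_geometry$center_x_um[idx] +
    (particles$x - (tile_geometry$width_px[idx] + 1) / 2) * px_um
  sy <- tile_geometry$center_y_um[idx] +
    (particles$y - (tile_geometry$height_px[idx] + 1) / 2) * px_um
  i <- round(um_to_index(sx, canvas$nx, canvas$extent_um[1]))
  j <- round(um_to_index(sy, canvas$ny, canvas$extent_um[2]))
  off <- i < 1 | i > canvas$nx | j < 1 | j > canvas$ny
  dose <- rep(NA_real_, nrow(particles))
  dose[!off] <- unclass(dose_map)[cbind(i[!off], j[!off])]
  particles$dose <- dose
  particles$off_canvas <- off
  particles
}

#' Split a particle table by the overdose rule
#'
#' Particles with annotated dose at or above the threshold are removed, the
#' rest kept; the two tables partition the input exactly.
#'
#' @param particles A [particle_table()] with `dose` annotated.
#' @param rule An [overdose_rule()].
#' @return List with `kept`, `removed` (particle tables, `kept` flag set)
#'   and `counts` (named vector: total, kept, removed).
#' @export
filter_overdosed <- function(particles, rule = overdose_rule()) {
  if (any(is.na(particles$dose)))
    stop("particles must be dose-annotated before filtering")
  over <- particles$dose >= rule$threshold_e_per_A2
  kept <- particles[!over, , drop = FALSE]
  removed <- particles[over, , drop = FALSE]
  if (nrow(kept)) kept$kept <- TRUE
  if (nrow(removed)) removed$kept <- FALSE
  list(kept = kept, removed = removed,
       counts = c(total = nrow(particles), kept = nrow(kept),
                  removed = nrow(removed)))
}

#' Map tile-frame particle coordinates into the montage frame
#'
#' Montage coordinate = tile coordinate + the tile's refined stitch offset
#' (relative to the montage origin).  `invert = TRUE` maps back; the round
#' trip is the identity.
#'
#' @param particles A [particle_table()] (coordinates in tile-frame pixels).
#' @param stitch A `stitch_result` from [stitch_tilt()], supplying refined
#'   per-tile positions, or a data frame `tile`, `x`, `y`.
#' @param invert Map montage-frame coordinates back to the tile frame.
#' @return The particle table with `x`, `y` shifted.
#' @export
map_to_montage <- function(particles, stitch, invert = FALSE) {
  pos <- if (inherits(stitch, "stitch_result")) stitch$positions else stitch
  idx <- match(particles$tomo, pos$tile)
  if (any(is.na(idx))) stop("unknown tile id in particle table")
  s <- if (invert) -1 else 1
  particles$x <- particles$x + s * pos$x[idx]
  particles$y <- particles$y + s * pos$y[idx]
  particles
}

#' Write / read a particle table as comma-separated text
#'
#' Columns: `id, tomo, x, y, z, dose, score, kept`.
#'
#' @param particles A [particle_table()].
#' @param path File path.
#' @return `write_particle_table` returns `path` invisibly;
#'   `read_particle_table` returns a `particle_table`.
#' @export
write_particle_table <- function(particles, path) {
  utils::write.csv(
    particles[, c("id", "tomo", "x", "y", "z", "dose", "score", "kept")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_particle_table
#' @export
read_particle_table <- function(path) {
  df <- utils::read.csv(path)
  out <- particle_table(df$id, df$tomo, df$x, df$y, df$z, df$dose, df$score)
  out$kept <- as.logical(df$kept)
  out
}

#' Convert a particle table to a 35-column Dynamo-style table
#'
#' Convenience writer only: id in column 1, shifts zeroed, coordinates in
#' columns 24--26, the remaining columns zero.
#'
#' @param particles A [particle_table()].
#' @return Numeric matrix with 35 columns, one row per particle.
#' @export
as_dynamo_table <- function(particles) {
  m <- matrix(0, nrow(particles), 35)
  m[, 1] <- particles$id
  m[, 24] <- particles$x
  m[, 25] <- particles$y
  m[, 26] <- particles$z
  m
}
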