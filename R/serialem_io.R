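# Acquisition-metadata dialects: mdoc sidecar files, acquisition macros and
# per-tilt piece-coordinate lists.
#
# All writers are deterministic (same input, byte-identical output).  The
# mdoc model stores every value as its raw text, so unknown keys round-trip
# verbatim; typed accessors parse the keys the pipeline needs.

fmt_num <- function(x) {
  # fixed decimal, up to 6 significant digits (common mdoc practice)
  vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(round(v)))
    else sub("0+$", "", sprintf("%.6f", signif(v, 6)))
  }, character(1))
}

fmt_full <- function(x) sprintf("%.17g", x)  # exact round-trip formatting

#' Construct an mdoc document
#'
#' @param header Named list of global key/value entries (values as text).
#' @param sections List of per-exposure sections; each a named list of
#'   key/value text entries with a `ZValue` attribute (integer).
#' @return An object of class `mdoc_document`.
#' @export
mdoc_document <- function(header = list(), sections = list()) {
  structure(list(header = header, sections = sections),
            class = "mdoc_document")
}

#' Read an mdoc metadata file
#'
#' Parses the key-value header and `[ZValue = n]` sections of a SerialEM
#' style mdoc sidecar.  Unknown keys are preserved verbatim and written back
#' unchanged by [write_mdoc()].
#'
#' @param path Path to an mdoc file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return An [mdoc_document()].
#' @export
read_mdoc <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  header <- list()
  sections <- list()
  cur <- NULL
  zval <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      if (is.null(zval)) stop("mdoc parse error: section without ZValue")
      attr(cur, "ZValue") <- zval
      sections[[length(sections) + 1L]] <<- cur
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    zm <- regmatches(ln, regexec("^\\[\\s*ZValue\\s*=\\s*(-?\\d+)\\s*\\]$", ln))[[1]]
    if (length(zm) == 2) {
      flush()
      cur <- list()
      zval <- as.integer(zm[2])
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3)
      stop("mdoc parse error: cannot parse line: ", ln)
    if (is.null(cur)) header[[kv[2]]] <- kv[3]
    else cur[[kv[2]]] <- kv[3]
  }
  flush()
  mdoc_document(header, sections)
}

#' Write an mdoc document
#'
#' @param doc An [mdoc_document()].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_mdoc <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "mdoc_document"))
  lines <- character(0)
  for (k in names(doc$header))
    lines <- c(lines, paste0(k, " = ", doc$header[[k]]))
  for (sec in doc$sections) {
    lines <- c(lines, "",
               sprintf("[ZValue = %d]", attr(sec, "ZValue")))
    for (k in names(sec))
      lines <- c(lines, paste0(k, " = ", sec[[k]]))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

mdoc_key_num <- function(doc, key) {
  lapply(doc$sections, function(sec) {
    v <- sec[[key]]
    if (is.null(v)) stop("mdoc section missing mandatory key: ", key)
    as.numeric(strsplit(trimws(v), "\\s+")[[1]])
  })
}

#' Typed accessors for mdoc sections
#'
#' @param doc An [mdoc_document()].
#' @return `mdoc_tilt_angles`: numeric vector; `mdoc_piece_coordinates`:
#'   integer matrix with columns x, y, z; `mdoc_image_shift`: numeric matrix
#'   with columns x, y (micrometres).
#' @export
mdoc_tilt_angles <- function(doc) {
  vapply(mdoc_key_num(doc, "TiltAngle"), `[[`, numeric(1), 1)
}

#' @rdname mdoc_tilt_angles
#' @export
mdoc_piece_coordinates <- function(doc) {
  m <- do.call(rbind, mdoc_key_num(doc, "PieceCoordinates"))
  storage.mode(m) <- "integer"
  colnames(m) <- c("x", "y", "z")
  m
}

#' @rdname mdoc_tilt_angles
#' @export
mdoc_image_shift <- function(doc) {
  m <- do.call(rbind, mdoc_key_num(doc, "ImageShift"))
  colnames(m) <- c("x", "y")
  m
}

#' Build an mdoc document for a montage acquisition
#'
#' One section per exposure (tilt x tile), ordered by acquisition, carrying
#' `TiltAngle`, `PieceCoordinates` (frame pixels, z = tilt index),
#' `ImageShift` (micrometres, relative to the centre tile) and
#' `ExposureDose`.
#'
#' @param frame A [camera_frame()].
#' @param pattern A [montage_pattern()].
#' @param scheme A [tilt_scheme()].
#' @param dose_per_exposure Exposure dose recorded per section.
#' @return An [mdoc_document()].
#' @export
build_montage_mdoc <- function(frame, pattern, scheme,
                               dose_per_exposure = 1) {
  grid <- tile_grid(pattern, frame)
  angles <- generate_tilt_angles(scheme)
  header <- list(
    PixelSpacing = fmt_num(frame$pixel_size_A),
    ImageSize = paste(frame$width_px, frame$height_px)
  )
  sections <- list()
  z <- 0L
  for (i in seq_along(angles)) {
    for (t in seq_len(nrow(grid))) {
      sections[[z + 1L]] <- structure(
        list(
          TiltAngle = fmt_num(angles[i]),
          PieceCoordinates = paste(grid$piece_x[t], grid$piece_y[t], i - 1L),
          ImageShift = paste(fmt_num(grid$shift_x_um[t]),
                             fmt_num(grid$shift_y_um[t])),
          ExposureDose = fmt_num(dose_per_exposure)
        ),
        ZValue = z
      )
      z <- z + 1L
    }
  }
  mdoc_document(header, sections)
}

#' Export an acquisition macro for a batch montage tilt series
#'
#' Writes a descriptive SerialEM-style macro enumerating, per tilt, the tilt
#' command, the translational pattern offset from the offset table and the
#' per-tile image-shift vectors, plus tracking thresholds (5 % of the FOV
#' below 30 deg, 10 % above, pause after 5 alignment iterations) and the
#' focus/tracking placement.  The macro encodes the plan faithfully but is
#' validated only by [parse_macro()]; it is not guaranteed runnable on a
#' microscope.
#'
#' Offsets are printed with full precision so that parsing the macro
#' recovers the offset table exactly.
#'
#' @param frame A [camera_frame()].
#' @param beam A [beam_illumination()].
#' @param pattern A [montage_pattern()].
#' @param scheme A [tilt_scheme()].
#' @param offsets An `offset_table` (one row per tilt, acquisition order).
#' @param dialect `"4.1"` (Multiple Record Montage parameter block) or
#'   `"3.8"` (MultishotParams-style block).
#' @return Character vector of macro lines.
#' @export
export_macro <- function(frame, beam, pattern, scheme, offsets,
                         dialect = c("4.1", "3.8")) {
  if (length(dialect) == 1 && !dialect %in% c("4.1", "3.8"))
    stop("unknown macro dialect: ", dialect)
  dialect <- match.arg(dialect)
  grid <- tile_grid(pattern, frame)
  angles <- generate_tilt_angles(scheme)
  stopifnot(nrow(offsets) == length(angles),
            all(abs(offsets$angle_deg - angles) < 1e-9))
  clamp <- attr(offsets, "max_offset_um")
  if (is.null(clamp) || is.na(clamp))
    clamp <- max(sqrt(offsets$dx_um^2 + offsets$dy_um^2))
  focus <- focus_tracking_position(pattern, frame, clamp)
  lines <- c(
    "MacroName MontageTiltSeries",
    sprintf("# Dialect %s", dialect),
    sprintf("# Pattern %d %d", pattern$m, pattern$n),
    sprintf("# OverlapPx %d %d", pattern$overlap_x_px, pattern$overlap_y_px),
    sprintf("# PixelSizeA %s", fmt_full(frame$pixel_size_A)),
    sprintf("# BeamDiameterUm %s", fmt_full(beam$diameter_um)),
    sprintf("# OffsetMode %s", attr(offsets, "mode")),
    sprintf("# MaxOffsetUm %s", fmt_full(clamp)),
    sprintf("FocusTrackingPosition %s %s", fmt_full(focus["x"]),
            fmt_full(focus["y"])),
    "TrackingThresholdLowTilt 0.05",
    "TrackingThresholdHighTilt 0.10",
    "TrackingThresholdSwitchDeg 30",
    "PauseAfterIterations 5"
  )
  if (dialect == "4.1") {
    lines <- c(lines, "MontageSetup",
               sprintf("  Tiles %d %d", pattern$m, pattern$n),
               sprintf("  OverlapPx %d %d", pattern$overlap_x_px,
                       pattern$overlap_y_px),
               "EndMontageSetup")
  } else {
    lines <- c(lines, "MultishotParams")
    for (t in seq_len(nrow(grid)))
      lines <- c(lines, sprintf("  ShotShift %d %s %s", grid$tile[t],
                                fmt_full(grid$shift_x_um[t]),
                                fmt_full(grid$shift_y_um[t])))
    lines <- c(lines, "EndMultishotParams")
  }
  for (i in seq_along(angles)) {
    lines <- c(lines,
               sprintf("# Tilt block %d", i),
               sprintf("TiltTo %s", fmt_full(angles[i])),
               sprintf("PatternOffset %s %s", fmt_full(offsets$dx_um[i]),
                       fmt_full(offsets$dy_um[i])),
               "MultipleRecord")
  }
  c(lines, "EndMacro")
}

#' Parse an exported acquisition macro
#'
#' Recovers the per-tilt offset table (and basic plan metadata) from a macro
#' written by [export_macro()]; the round trip is exact.
#'
#' @param lines Character vector of macro lines.
#' @return List with `offsets` (an `offset_table`), `dialect`, `pattern_mn`,
#'   `mode`, `max_offset_um`.
#' @export
parse_macro <- function(lines) {
  get1 <- function(pattern) {
    m <- regmatches(lines, regexec(pattern, lines))
    m <- m[vapply(m, length, integer(1)) > 1]
    if (length(m) == 0) stop("macro parse error: missing ", pattern)
    m[[1]][-1]
  }
  dialect <- get1("^# Dialect (.+)$")
  mn <- as.integer(get1("^# Pattern (\\d+) (\\d+)$"))
  mode <- get1("^# OffsetMode (.+)$")
  clamp <- as.numeric(get1("^# MaxOffsetUm (.+)$"))
  tilt <- as.numeric(sub("^TiltTo ", "", grep("^TiltTo ", lines, value = TRUE)))
  off <- grep("^PatternOffset ", lines, value = TRUE)
  offm <- do.call(rbind, lapply(strsplit(sub("^PatternOffset ", "", off),
                                         " "), as.numeric))
  stopifnot(length(tilt) == nrow(offm))
  offsets <- structure(
    data.frame(tilt_index = seq_along(tilt) - 1L, angle_deg = tilt,
               dx_um = offm[, 1], dy_um = offm[, 2]),
    mode = mode, max_offset_um = clamp,
    class = c("offset_table", "data.frame")
  )
  list(offsets = offsets, dialect = dialect, pattern_mn = mn, mode = mode,
       max_offset_um = clamp)
}

#' Per-tilt piece coordinates
#'
#' Nominal piece coordinates at tilt alpha: the y component is scaled by
#' cos(alpha) because specimen content spacing perpendicular to the tilt
#' axis foreshortens while the image-shift tile spacing stays fixed, so
#' y-adjacent tiles overlap more at high tilt.
#'
#' @param grid A tile grid from [tile_grid()].
#' @param alpha_deg Tilt angle.
#' @return Data frame `tile`, `piece_x`, `piece_y` (numeric pixels).
#' @export
piece_coords_at_tilt <- function(grid, alpha_deg) {
  data.frame(tile = grid$tile, piece_x = grid$piece_x,
             piece_y = grid$piece_y * cospi(alpha_deg / 180))
}

#' Write per-tilt piece-coordinate list files
#'
#' One file per tilt, ordered by tilt angle (most negative first), each with
#' m x n lines of integer `x y z` piece coordinates (z = section index of
#' the tilt in the angle-sorted order).
#'
#' @param pattern A [montage_pattern()].
#' @param frame A [camera_frame()].
#' @param angles Tilt angles (any order; files are written angle-sorted).
#' @param dir Output directory (created if needed).
#' @param cosine_scaled Scale y coordinates by cos(alpha) per tilt.
#' @return Character vector of file paths, in angle order.
#' @export
write_piece_lists <- function(pattern, frame, angles, dir,
                              cosine_scaled = TRUE) {
  grid <- tile_grid(pattern, frame)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- order(angles)
  paths <- character(length(angles))
  for (s in seq_along(ord)) {
    a <- angles[ord[s]]
    pc <- if (cosine_scaled) piece_coords_at_tilt(grid, a)
          else data.frame(piece_x = grid$piece_x, piece_y = grid$piece_y)
    path <- file.path(dir, sprintf("pieces_%03d_%+.1f.pl", s, a))
    writeLines(sprintf("%d %d %d", as.integer(round(pc$piece_x)),
                       as.integer(round(pc$piece_y)), s - 1L), path)
    paths[s] <- path
  }
  paths
}

#' Read a piece-coordinate list file
#'
#' @param path Path to a `.pl` file written by [write_piece_lists()].
#' @return Integer matrix with columns x, y, z.
#' @export
read_piece_list <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  storage.mode(m) <- "integer"
  m
}
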