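# YAML acquisition configuration.

#' Read an acquisition configuration file
#'
#' Expects a YAML document with blocks `camera` (width_px, height_px,
#' pixel_size_A), `beam` (diameter_um, fringe_fraction_x), `pattern` (m, n,
#' overlap_x_px, overlap_y_px), `tilt` (max_deg, increment_deg, group_size,
#' style) and optionally `spiral` (A_final, period, turns, revolutions).
#' See `system.file("extdata", "benchmark.yaml", package = "tomomontage")`
#' for the benchmarked acquisition state.
#'
#' @param path Path to a YAML configuration file.
#' @return Named list with elements `frame`, `beam`, `pattern`, `scheme`
#'   and (when present) `spiral`, as package objects.
#' @export
read_acquisition_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(block, keys) {
    b <- cfg[[block]]
    if (is.null(b)) stop("configuration missing block: ", block)
    miss <- setdiff(keys, names(b))
    if (length(miss))
      stop("configuration block '", block, "' missing: ",
           paste(miss, collapse = ", "))
    b
  }
  cam <- need("camera", c("width_px", "height_px", "pixel_size_A"))
  bm <- need("beam", "diameter_um")
  # a bare `n:` key is a YAML-1.1 boolean; accept either spelling
  if (!is.null(cfg$pattern) && is.null(cfg$pattern$n) &&
      "FALSE" %in% names(cfg$pattern))
    cfg$pattern$n <- cfg$pattern[["FALSE"]]
  pat <- need("pattern", c("m", "n", "overlap_x_px", "overlap_y_px"))
  tl <- need("tilt", c("max_deg", "increment_deg"))
  out <- list(
    frame = camera_frame(cam$width_px, cam$height_px, cam$pixel_size_A),
    beam = beam_illumination(bm$diameter_um,
                             bm$fringe_fraction_x %||% 0.04),
    pattern = montage_pattern(pat$m, pat$n, pat$overlap_x_px,
                              pat$overlap_y_px),
    scheme = tilt_scheme(tl$max_deg, tl$increment_deg,
                         tl$group_size %||% 1,
                         tl$style %||% "dose-symmetric")
  )
  if (!is.null(cfg$spiral)) {
    sp <- cfg$spiral
    out$spiral <- spiral_params(sp$A_final %||% 1.5, sp$period %||% 3,
                                sp$turns %||% 50, sp$revolutions %||% 15)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
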