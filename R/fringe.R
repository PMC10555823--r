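# Fresnel-fringe cutoff calibration from a gain-normalized beam image.
#
# The beam-defining aperture rings the illuminated-area edge with Fresnel
# fringes that contaminate the frame periphery.  The calibration low-pass
# filters the image to 50 A to enhance the fringe peaks, fits the outer
# edge band as a Poisson "signal" distribution and the image centre as a
# Gaussian "noise" background, and reports the outermost x depth at which
# the edge profile's excursions still exit the mu +/- 2 sigma background
# band, averaged over multiple traversals.

# Gaussian low-pass to a resolution (A) via FFT; sampling in A/px.
lowpass_filter <- function(img, pixel_size_A, resolution_A = 50) {
  nx <- nrow(img); ny <- ncol(img)
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx / pixel_size_A
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny / pixel_size_A
  fc <- 1 / resolution_A
  f2 <- outer(fx^2, fy^2, `+`)
  H <- exp(-f2 / (2 * fc^2))  # ~ half amplitude at the cutoff frequency
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (nx * ny)
}

#' Fit the fringe-impacted cutoff fraction of a beam image
#'
#' @param image 2D gain-normalized beam image (`[x, y]` matrix) or a
#'   `fringed_beam` fixture.
#' @param pixel_size_A Sampling, Angstrom per pixel.
#' @param resolution_A Low-pass resolution applied before fitting (50 A).
#' @param edge_fraction Fraction of x and y defining the outer edge band
#'   fitted as the Poisson signal (0.20).
#' @param center_fraction Fraction of the dimensions, from the centre out,
#'   fitted as the Gaussian background (0.90; overlaps the edge band).
#' @param n_strips Number of y strips per x edge used as independent
#'   traversals of the fringe profile (>= 3 measurements total).
#' @return Object of class `fringe_fit`: `cutoff_fraction_x` (mean over
#'   traversals), `cutoff_fraction_y` (reported, expected near 0),
#'   `lambda_edge`, `mu_bg`, `sigma_bg`, `per_edge` (per-traversal
#'   fractions) and `profiles` (per-edge mean-intensity profiles).
#' @examples
#' fb <- make_fringed_beam(seed = 2, depth_fraction = 0.04)
#' fit <- fit_fringe_cutoff(fb)
#' fit$cutoff_fraction_x
#' @export
fit_fringe_cutoff <- function(image, pixel_size_A = NULL,
                              resolution_A = 50, edge_fraction = 0.20,
                              center_fraction = 0.90, n_strips = 2) {
  if (inherits(image, "fringed_beam")) {
    if (is.null(pixel_size_A)) pixel_size_A <- image$pixel_size_A
    image <- image$image
  }
  stopifnot(is.matrix(image), !is.null(pixel_size_A))
  if (any(!is.finite(image))) stop("non-finite pixels in beam image")
  nx <- nrow(image); ny <- ncol(image)
  if (nx < 20 || ny < 20)
    stop("image smaller than the band definitions")
  img <- lowpass_filter(image, pixel_size_A, resolution_A)

  # Gaussian background: central region, center_fraction of each dimension
  cb <- function(n, frac) {
    half <- floor(n * frac / 2)
    (n %/% 2 - half + 1):(n %/% 2 + half)
  }
  centre <- img[cb(nx, center_fraction), cb(ny, center_fraction)]
  gfit <- MASS::fitdistr(as.vector(centre), "normal")
  mu <- unname(gfit$estimate["mean"])
  sigma <- unname(gfit$estimate["sd"])

  # Poisson signal: outer edge band, integerized after offset removal
  d_edge <- max(1L, floor(edge_fraction * min(nx, ny)))
  edge_mask <- matrix(FALSE, nx, ny)
  edge_mask[c(seq_len(d_edge), nx - seq_len(d_edge) + 1L), ] <- TRUE
  edge_mask[, c(seq_len(d_edge), ny - seq_len(d_edge) + 1L)] <- TRUE
  counts <- round((img[edge_mask] - min(img)) / max(sigma, 1e-12))
  pfit <- MASS::fitdistr(pmax(counts, 0), "poisson")
  lambda <- unname(pfit$estimate["lambda"])

  # Edge profiles: mean over y strips of columns stepping in from each x
  # edge; cutoff depth = outermost depth whose excursion exits mu +/- 2 s.
  max_depth <- floor(0.4 * nx)
  strip_bounds <- floor(seq(1, ny + 1, length.out = n_strips + 1))
  traversals <- list()
  for (s in seq_len(n_strips)) {
    rows <- strip_bounds[s]:(strip_bounds[s + 1] - 1)
    prof_l <- colMeans(t(img[seq_len(max_depth), rows, drop = FALSE]))
    prof_r <- colMeans(t(img[nx - seq_len(max_depth) + 1L, rows,
                             drop = FALSE]))
    traversals <- c(traversals, list(left = prof_l, right = prof_r))
  }
  cutoff_depth <- function(prof) {
    out <- abs(prof - mu) > 2 * sigma
    if (!any(out)) 0L else max(which(out))
  }
  per_edge <- vapply(traversals, cutoff_depth, numeric(1)) / nx
  cutoff_x <- mean(per_edge)

  # y direction, fitted the same way (expected ~ 0 for the benchmark beam)
  max_depth_y <- floor(0.4 * ny)
  prof_b <- rowMeans(t(img)[seq_len(max_depth_y), , drop = FALSE])
  prof_t <- rowMeans(t(img)[ny - seq_len(max_depth_y) + 1L, , drop = FALSE])
  cutoff_y <- mean(c(cutoff_depth(prof_b), cutoff_depth(prof_t))) / ny

  structure(
    list(cutoff_fraction_x = cutoff_x, cutoff_fraction_y = cutoff_y,
         lambda_edge = lambda, mu_bg = mu, sigma_bg = sigma,
         per_edge = per_edge, profiles = traversals),
    class = "fringe_fit"
  )
}

#' @export
print.fringe_fit <- function(x, ...) {
  cat(sprintf(
    "fringe cutoff: %.3f of x per side (y: %.3f); background %.3g +/- %.3g\n",
    x$cutoff_fraction_x, x$cutoff_fraction_y, x$mu_bg, x$sigma_bg))
  invisible(x)
}
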