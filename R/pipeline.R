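# Two-path montage processing: sort frames into per-tile tilt series,
# stitch per-tilt montages (coordinate priors + cross-correlation
# refinement, least-squares global positions, linear feather blending),
# assemble stitched stacks, measure ROI drift, and reconstruct small test
# volumes by filtered back-projection.

#' Sort montage frames into per-tile tilt series
#'
#' Every frame maps to exactly one (tilt, tile) pair; the union of the
#' per-tile stacks is the input set with no duplication.  Tiles missing one
#' or more tilts are marked incomplete (their series would be discarded in
#' a real workflow).
#'
#' @param dataset A `montage_dataset` (see [make_montage_dataset()]).
#' @return Object of class `tile_sort`: `tiles` (per tile: `stack` list of
#'   frames ordered by angle, `angles`, `complete`, `missing_angles`),
#'   `by_tilt` (per tilt index: exposure row indices), `n_incomplete`.
#' @export
sort_tiles <- function(dataset) {
  meta <- dataset$meta
  all_tilts <- sort(unique(meta$tilt_index))
  tilt_angle <- meta$angle_deg[match(all_tilts, meta$tilt_index)]
  ord_ang <- order(tilt_angle)
  tile_ids <- sort(unique(meta$tile))
  tiles <- lapply(tile_ids, function(t) {
    rows <- meta[meta$tile == t, , drop = FALSE]
    have <- match(all_tilts[ord_ang], rows$tilt_index)
    missing <- is.na(have)
    stack <- vector("list", length(have))
    stack[!missing] <- dataset$frames[rows$exposure[have[!missing]]]
    list(tile = t, stack = stack[!missing],
         angles = tilt_angle[ord_ang][!missing],
         complete = !any(missing),
         missing_angles = tilt_angle[ord_ang][missing])
  })
  names(tiles) <- paste0("tile", tile_ids)
  by_tilt <- lapply(all_tilts, function(i) which(meta$tilt_index == i))
  names(by_tilt) <- paste0("tilt", all_tilts)
  structure(list(tiles = tiles, by_tilt = by_tilt,
                 n_incomplete = sum(!vapply(tiles, `[[`, logical(1),
                                            "complete"))),
            class = "tile_sort")
}

# Normalized cross-correlation of the overlap between two tiles for one
# candidate displacement of B relative to A; NA when either patch is flat.
ncc_at <- function(A, B, ox, oy) {
  W <- nrow(A); H <- ncol(A)
  x0 <- max(1L, 1L + ox); x1 <- min(W, W + ox)
  y0 <- max(1L, 1L + oy); y1 <- min(H, H + oy)
  if (x0 > x1 || y0 > y1) return(NA_real_)
  a <- A[x0:x1, y0:y1]
  b <- B[(x0:x1) - ox, (y0:y1) - oy]
  if (length(a) < 16) return(NA_real_)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0)
    return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

# Best relative offset of tile B vs tile A near the nominal relative offset,
# searching +/-radius px; ties broken toward the smallest displacement.
refine_pair <- function(A, B, rel_nominal, radius) {
  cand <- expand.grid(u = -radius:radius, v = -radius:radius)
  cand <- cand[order(cand$u^2 + cand$v^2), ]
  best <- -Inf; best_uv <- c(0, 0)
  for (r in seq_len(nrow(cand))) {
    s <- ncc_at(A, B, rel_nominal[1] + cand$u[r], rel_nominal[2] + cand$v[r])
    if (!is.na(s) && s > best + 1e-12) {
      best <- s
      best_uv <- c(cand$u[r], cand$v[r])
    }
  }
  list(score = if (is.finite(best)) best else NA_real_, duv = best_uv)
}

#' Stitch the tiles of one tilt
#'
#' Pairwise offsets between adjacent tiles are refined by normalized
#' cross-correlation over the nominal overlap bands, constrained to
#' `search_radius_px` of the nominal piece coordinates; global tile
#' positions are then solved by least squares over the adjacency graph,
#' anchored at the first tile, and the overlap is blended by linear
#' feathering.  Tiles whose every pair score falls below `peak_threshold`
#' (for instance featureless ice) fall back to their nominal coordinates
#' and are flagged, mirroring the manual-alignment fallback of real
#' processing.
#'
#' @param tiles List of frame matrices (`[x, y]`), one per tile.
#' @param layout Data frame with per-tile `tile`, `ix`, `iy`, `piece_x`,
#'   `piece_y` (nominal coordinates, possibly cosine-scaled in y).
#' @param refine Refine by cross-correlation (`FALSE`: nominal only).
#' @param search_radius_px Search half-width around nominal, pixels.
#' @param peak_threshold Minimum acceptable correlation peak.
#' @return Object of class `stitch_result`: `montage` (blended image),
#'   `origin` (pixel position of the montage's first pixel in layout
#'   coordinates),
#'   `positions` (refined per-tile positions), `nominal`, `pair_scores`,
#'   `flagged` (logical per tile).
#' @export
stitch_tilt <- function(tiles, layout, refine = TRUE, search_radius_px = 6,
                        peak_threshold = 0.1) {
  nt <- length(tiles)
  stopifnot(nt == nrow(layout), nt >= 1)
  W <- nrow(tiles[[1]]); H <- ncol(tiles[[1]])
  nominal <- cbind(x = layout$piece_x, y = layout$piece_y)
  # adjacency, with overlap sanity check
  pairs <- list()
  for (a in seq_len(nt)) {
    for (b in seq_len(nt)) {
      dxn <- layout$ix[b] - layout$ix[a]
      dyn <- layout$iy[b] - layout$iy[a]
      if ((dxn == 1L && dyn == 0L) || (dxn == 0L && dyn == 1L)) {
        # adjacent tiles must be able to overlap within the search radius
        r <- if (refine) search_radius_px else 0
        if (abs(nominal[b, 1] - nominal[a, 1]) >= W + r ||
            abs(nominal[b, 2] - nominal[a, 2]) >= H + r)
          stop("non-overlapping nominal layout")
        pairs[[length(pairs) + 1L]] <- c(a, b)
      }
    }
  }
  scores <- data.frame(a = integer(0), b = integer(0), score = numeric(0),
                       du = numeric(0), dv = numeric(0))
  if (refine && length(pairs)) {
    for (p in pairs) {
      rel <- round(nominal[p[2], ] - nominal[p[1], ])
      rf <- refine_pair(tiles[[p[1]]], tiles[[p[2]]], rel, search_radius_px)
      scores <- rbind(scores, data.frame(
        a = p[1], b = p[2], score = rf$score,
        du = rel[1] + rf$duv[1] - (nominal[p[2], 1] - nominal[p[1], 1]),
        dv = rel[2] + rf$duv[2] - (nominal[p[2], 2] - nominal[p[1], 2])))
    }
  }
  ok <- !is.na(scores$score) & scores$score >= peak_threshold
  flagged <- rep(TRUE, nt)
  if (any(ok)) flagged[unique(c(scores$a[ok], scores$b[ok]))] <- FALSE
  if (!refine) flagged <- rep(FALSE, nt)

  positions <- nominal
  if (refine && any(ok)) {
    # weighted least squares per axis: pair rows p_b - p_a = measured,
    # anchor + flagged tiles pinned to nominal, weak prior for rank safety
    for (axis in 1:2) {
      rows <- list(); rhs <- c(); wts <- c()
      add <- function(coef, b, w) {
        rows[[length(rows) + 1L]] <<- coef
        rhs <<- c(rhs, b); wts <<- c(wts, w)
      }
      unit <- function(i, s = 1) { v <- numeric(nt); v[i] <- s; v }
      add(unit(1), nominal[1, axis], 1e6)
      for (i in which(flagged)) add(unit(i), nominal[i, axis], 1e6)
      for (r in which(ok)) {
        meas <- nominal[scores$b[r], axis] - nominal[scores$a[r], axis] +
          (if (axis == 1) scores$du[r] else scores$dv[r])
        add(unit(scores$b[r]) - unit(scores$a[r]), meas, 1)
      }
      for (i in seq_len(nt)) add(unit(i), nominal[i, axis], 1e-3)
      Amat <- do.call(rbind, rows) * sqrt(wts)
      sol <- qr.solve(Amat, rhs * sqrt(wts))
      positions[, axis] <- sol
    }
    # refined offsets stay within the search radius of nominal
    positions <- pmin(pmax(positions, nominal - search_radius_px),
                      nominal + search_radius_px)
  }

  # blend with separable linear feathering over the overlap bands
  pi_ <- round(positions)
  x0 <- min(pi_[, 1]); y0 <- min(pi_[, 2])
  cw <- max(pi_[, 1]) - x0 + W
  ch <- max(pi_[, 2]) - y0 + H
  fx <- max(1, W - round(min(diff(sort(unique(nominal[, 1]))), W)))
  fy <- max(1, H - round(min(diff(sort(unique(nominal[, 2]))), H)))
  wx <- pmin(seq_len(W), rev(seq_len(W)), fx) / fx
  wy <- pmin(seq_len(H), rev(seq_len(H)), fy) / fy
  wt <- outer(wx, wy)
  num <- matrix(0, cw, ch); den <- matrix(0, cw, ch)
  for (t in seq_len(nt)) {
    xi <- (pi_[t, 1] - x0) + seq_len(W)
    yi <- (pi_[t, 2] - y0) + seq_len(H)
    num[xi, yi] <- num[xi, yi] + tiles[[t]] * wt
    den[xi, yi] <- den[xi, yi] + wt
  }
  montage <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
  structure(
    list(montage = montage, origin = c(x = x0, y = y0),
         positions = data.frame(tile = layout$tile, x = positions[, 1],
                                y = positions[, 2]),
         nominal = data.frame(tile = layout$tile, x = nominal[, 1],
                              y = nominal[, 2]),
         pair_scores = scores, flagged = flagged),
    class = "stitch_result"
  )
}

#' Assemble stitched per-tilt montages into a tilt-series stack
#'
#' Crops every stitched montage to the common region (the intersection of
#' the per-tilt extents in the shared layout coordinates).  Because content
#' spacing perpendicular to the tilt axis shrinks as y cos(alpha), per-tilt
#' stitching yields smaller y extents at high tilt, so the common region is
#' set by the highest tilts.
#'
#' @param results List of `stitch_result`s, in the desired stack order.
#' @return Numeric array `[x, y, tilt]` with attribute `extents` (per-tilt
#'   data frame of x/y sizes before cropping).
#' @export
assemble_montage_stack <- function(results) {
  stopifnot(length(results) >= 1)
  ext <- do.call(rbind, lapply(results, function(r)
    data.frame(x0 = r$origin["x"], y0 = r$origin["y"],
               w = nrow(r$montage), h = ncol(r$montage))))
  X0 <- max(ext$x0); X1 <- min(ext$x0 + ext$w)
  Y0 <- max(ext$y0); Y1 <- min(ext$y0 + ext$h)
  if (X1 <= X0 || Y1 <= Y0) stop("empty common region across tilts")
  stack <- array(0, dim = c(X1 - X0, Y1 - Y0, length(results)))
  for (i in seq_along(results)) {
    r <- results[[i]]
    stack[, , i] <- r$montage[(X0 - r$origin["x"]) + seq_len(X1 - X0),
                              (Y0 - r$origin["y"]) + seq_len(Y1 - Y0)]
  }
  attr(stack, "extents") <- ext
  stack
}

# Integer-pixel cross-correlation peak: shift of `img` relative to `ref`,
# searched within +/-max_shift (FFT correlation, mean-removed).
cc_peak <- function(img, ref, max_shift = NULL) {
  stopifnot(all(dim(img) == dim(ref)))
  if (stats::sd(ref) == 0 || stats::sd(img) == 0)
    stop("degenerate (constant) frames in cross-correlation")
  nx <- nrow(img); ny <- ncol(img)
  if (is.null(max_shift)) max_shift <- floor(min(nx, ny) / 4)
  # Hann apodization suppresses the circular-wrap edge terms that otherwise
  # bias the peak toward zero shift on structured frames
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  wnd <- outer(hann(nx), hann(ny))
  A <- (img - mean(img)) * wnd
  B <- (ref - mean(ref)) * wnd
  C <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE))
  sx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  sy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  mask <- outer(abs(sx) <= max_shift, abs(sy) <= max_shift)
  C[!mask] <- -Inf
  k <- arrayInd(which.max(C), dim(C))
  c(dx = sx[k[1]], dy = sy[k[2]])
}

#' Per-tilt ROI drift of a tile tilt series
#'
#' Each tilted frame is stretched by 1/cos(alpha) along y (undoing
#' foreshortening), then cross-correlated against the reference (0 deg)
#' frame; the peak displacement, converted to nanometres, measures how far
#' the region of interest wandered from its 0 deg position.
#'
#' @param stack List of frame matrices ordered by angle.
#' @param angles Tilt angles matching `stack`.
#' @param pixel_size_A Frame sampling, Angstrom per pixel.
#' @param max_shift_px Search limit for the correlation peak.
#' @return Data frame `angle_deg`, `dx_px`, `dy_px`, `displacement_nm`.
#' @export
drift_metric <- function(stack, angles, pixel_size_A,
                         max_shift_px = NULL) {
  stopifnot(length(stack) == length(angles))
  iref <- which.min(abs(angles))
  ref <- stack[[iref]]
  out <- data.frame(angle_deg = angles, dx_px = NA_real_, dy_px = NA_real_,
                    displacement_nm = NA_real_)
  for (i in seq_along(stack)) {
    stretched <- stretch_y(stack[[i]], cospi(angles[i] / 180))
    pk <- cc_peak(stretched, ref, max_shift_px)
    out$dx_px[i] <- pk["dx"]
    out$dy_px[i] <- pk["dy"]
    out$displacement_nm[i] <-
      sqrt(sum(pk^2)) * pixel_size_A / 10
  }
  out
}

# Resample a frame along y about its centre: output(y) = input(cy + (y-cy)*f)
# with linear interpolation; f = cos(alpha) stretches the frame by 1/cos.
stretch_y <- function(img, f) {
  H <- ncol(img)
  cy <- (H + 1) / 2
  ys <- cy + (seq_len(H) - cy) * f
  j0 <- pmin(pmax(floor(ys), 1), H - 1)
  w <- pmin(pmax(ys - j0, 0), 1)
  img[, j0] * rep(1 - w, each = nrow(img)) +
    img[, j0 + 1] * rep(w, each = nrow(img))
}

#' Filtered back-projection about the x tilt axis
#'
#' A minimal deterministic ramp-filtered back-projector for testing: each
#' projection is filtered along y and smeared back through the volume along
#' the beam direction at its tilt angle.  Real data should use an
#' established tomography package; this exists so the two-path contract and
#' point-feature fidelity can be tested end to end.
#'
#' @param stack Numeric array `[x, y, tilt]` of aligned projections.
#' @param angles Tilt angles, one per stack slice.
#' @param thickness Output z thickness in voxels.
#' @param filter `"ramp"` or `"none"` (with `"none"` and a single 0 deg
#'   projection the slice equals the input).
#' @return Numeric array `[x, y, z]`.
#' @export
reconstruct <- function(stack, angles, thickness,
                        filter = c("ramp", "none")) {
  filter <- match.arg(filter)
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] == length(angles),
            thickness >= 1)
  nx <- dim(stack)[1]; ny <- dim(stack)[2]; nz <- as.integer(thickness)
  vol <- array(0, dim = c(nx, ny, nz))
  cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  Y <- rep(seq_len(ny), times = nz)
  Z <- rep(seq_len(nz), each = ny)
  ramp <- NULL
  if (filter == "ramp") {
    fr <- c(0:(ny %/% 2), (ny - ny %/% 2 - 1):1) / ny
    ramp <- pmax(fr, 1 / ny)  # keep a little DC so means survive
  }
  for (i in seq_along(angles)) {
    P <- stack[, , i]
    if (!is.null(ramp)) {
      Pf <- t(apply(P, 1, function(row)
        Re(stats::fft(stats::fft(row) * ramp, inverse = TRUE)) / ny))
      P <- Pf
    }
    ca <- cospi(angles[i] / 180); sa <- sinpi(angles[i] / 180)
    p <- (Y - cy) * ca + (Z - cz) * sa + cy
    valid <- p >= 1 & p <= ny
    j0c <- pmin(pmax(floor(p), 1), ny - 1)
    w <- pmin(pmax(p - j0c, 0), 1)
    contrib <- P[, j0c, drop = FALSE] * rep(1 - w, each = nx) +
      P[, j0c + 1, drop = FALSE] * rep(w, each = nx)
    contrib[, !valid] <- 0
    vol <- vol + array(contrib, dim = c(nx, ny, nz))
  }
  vol / length(angles)
}

#' Run the two processing paths of a montage dataset
#'
#' Path 1 stitches every tilt (cosine-scaled coordinate priors plus
#' cross-correlation), assembles the stitched tilt-series stack and
#' reconstructs one montage tomogram.  Path 2 sorts the frames into
#' individual tile tilt series and reconstructs each complete tile.  An
#' m x n dataset therefore yields m x n + 1 volumes.
#'
#' @param dataset A `montage_dataset`.
#' @param thickness Reconstruction thickness in voxels.
#' @param refine Passed to [stitch_tilt()].
#' @param search_radius_px Passed to [stitch_tilt()].
#' @return Object of class `two_path_result`: `stitched` (volume),
#'   `tile_volumes` (list, one per complete tile), `n_volumes`,
#'   `stitch_results`, `sorted` (the [sort_tiles()] output).
#' @export
run_two_paths <- function(dataset, thickness = 16, refine = TRUE,
                          search_radius_px = 6) {
  grid <- tile_grid(dataset$pattern, dataset$frame)
  meta <- dataset$meta
  tilt_ids <- sort(unique(meta$tilt_index))
  tilt_angle <- meta$angle_deg[match(tilt_ids, meta$tilt_index)]
  ord <- order(tilt_angle)

  results <- vector("list", length(ord))
  for (s in seq_along(ord)) {
    i <- tilt_ids[ord[s]]
    a <- tilt_angle[ord[s]]
    rows <- meta[meta$tilt_index == i, , drop = FALSE]
    rows <- rows[order(rows$tile), , drop = FALSE]
    tiles <- dataset$frames[rows$exposure]
    pc <- piece_coords_at_tilt(grid, a)
    layout <- data.frame(tile = grid$tile, ix = grid$ix, iy = grid$iy,
                         piece_x = pc$piece_x, piece_y = pc$piece_y)
    results[[s]] <- stitch_tilt(tiles, layout, refine = refine,
                                search_radius_px = search_radius_px)
  }
  stack <- assemble_montage_stack(results)
  stitched <- reconstruct(stack, tilt_angle[ord], thickness)

  sorted <- sort_tiles(dataset)
  complete <- Filter(function(t) t$complete, sorted$tiles)
  tile_volumes <- lapply(complete, function(t) {
    arr <- array(unlist(t$stack),
                 dim = c(nrow(t$stack[[1]]), ncol(t$stack[[1]]),
                         length(t$stack)))
    reconstruct(arr, t$angles, thickness)
  })
  structure(
    list(stitched = stitched, tile_volumes = tile_volumes,
         n_volumes = 1L + length(tile_volumes),
         stitch_results = results, sorted = sorted),
    class = "two_path_result"
  )
}
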