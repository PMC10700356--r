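# Kymograph construction and retrograde-flow estimation.

#' Build a kymograph along a polyline
#'
#' Per frame, intensity is sampled along the polyline (resampled to 1-px
#' arc spacing, bilinear) and averaged across `width_px` perpendicular
#' offsets; rows are arc position, columns are time.
#'
#' @param movie a [cell_movie()] time series.
#' @param line polyline as a two-column (x, y) pixel matrix.
#' @param width_px averaging width perpendicular to the line.
#' @param channel channel to sample.
#' @return a `kymograph`: list with `data` (space x time), `pixel_size_um`,
#'   `dt_s`, `line`.
#' @export
build_kymograph <- function(movie, line, width_px = 5, channel = "actin") {
  stopifnot(movie$axis_kind == "time")
  if (any(line[, 1] < 1) || any(line[, 2] < 1) ||
      any(line[, 1] > dim(movie$data)[4]) || any(line[, 2] > dim(movie$data)[3])) {
    abort("polyline lies outside the image")
  }
  rs <- resample_polyline(line, step = 1)
  n <- nrow(rs)
  # unit normals for width averaging
  nxt <- rs[pmin(n, 2:(n + 1))[seq_len(n)], , drop = FALSE]
  prv <- rs[pmax(1, 0:(n - 1))[seq_len(n)], , drop = FALSE]
  tx <- nxt[, 1] - prv[, 1]; ty <- nxt[, 2] - prv[, 2]
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nx <- -ty / tl; ny <- tx / tl
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 1)
  n_t <- dim(movie$data)[1]
  km <- matrix(0, n, n_t)
  for (t in seq_len(n_t)) {
    img <- movie_frame(movie, t, channel)
    acc <- numeric(n)
    for (o in offs) {
      acc <- acc + bilinear_sample(img, rs[, 1] + o * nx, rs[, 2] + o * ny)
    }
    km[, t] <- acc / length(offs)
  }
  structure(list(data = km, pixel_size_um = movie$pixel_size_um,
                 dt_s = movie$dt_s, line = rs),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d px x %d frames @ %.4f um/px, dt %.3g s\n",
              nrow(x$data), ncol(x$data), x$pixel_size_um, x$dt_s))
  invisible(x)
}

#' Estimate flow speed from a kymograph
#'
#' Finds the dominant stripe orientation by Radon-style projection: for
#' each candidate slope the kymograph is sheared so stripes of that slope
#' become horizontal, rows are averaged over time, and the slope
#' maximizing the variance of the averaged profile wins (with parabolic
#' refinement on the slope grid). Speed is `|slope| * pixel / dt`,
#' reported as a magnitude in um/min; invariant to intensity scaling and
#' offsets, and to time reversal.
#'
#' @param kymo a `kymograph` (at least 8 x 8).
#' @param max_slope_px maximum |slope| scanned, px/frame (default limits
#'   the stripe to crossing half the kymograph).
#' @return tibble: `flow_um_min`, `slope_px_per_frame`, `contrast`
#'   (peak-to-mean variance ratio), `indeterminate` flag.
#' @export
estimate_flow <- function(kymo, max_slope_px = NULL) {
  km <- kymo$data
  if (nrow(km) < 8 || ncol(km) < 8) abort("kymograph must be at least 8x8")
  n_s <- nrow(km); n_t <- ncol(km)
  if (is.null(max_slope_px)) max_slope_px <- max(1, (n_s - 1) / (n_t - 1) / 0.5)
  km <- sweep(km, 2, colMeans(km))   # remove temporal offsets
  # light spatial smoothing knocks down pixel-level noise without moving
  # the stripe orientation
  if (n_s > 4) {
    km <- (km + rbind(km[1, ], km[-n_s, ]) + rbind(km[-1, ], km[n_s, ])) / 3
  }
  # separate the static row profile from the time-varying part: structures
  # that never move are not flow (and would otherwise pull the slope toward
  # zero). A kymograph with *no* time-varying structure is stationary.
  static <- rowMeans(km)
  resid <- km - static
  if (mean(resid^2) < 1e-10 * (var(static) + 1e-12)) {
    return(tibble(flow_um_min = 0, slope_px_per_frame = 0,
                  contrast = Inf, indeterminate = var(static) == 0))
  }
  km <- resid
  # Score a candidate slope by shearing so stripes of that slope become
  # horizontal and decomposing the sheared kymograph into between-row and
  # within-row variance (a random-effects decomposition): aligned stripes
  # put variance between rows, misaligned ones within rows. Subtracting
  # the within-row noise floor makes scores comparable across window
  # lengths, so the averaging window can adapt to the slope (fast stripes
  # stay in the field of view only over short windows).
  score_of <- function(v) {
    L <- if (abs(v) < 1e-9) n_t else
      max(12, min(n_t, ceiling(18 / abs(v))))
    n_w <- max(1, floor(n_t / L))
    tot <- 0
    used <- 0
    for (w in seq_len(n_w)) {
      win <- ((w - 1) * L + 1):(w * L)
      tt <- win - mean(win)
      shifts <- v * tt
      lo <- 1 - min(shifts); hi <- n_s - max(shifts)
      rows <- seq(ceiling(lo), floor(hi))
      if (length(rows) < 6) next
      vals <- vapply(seq_along(win), function(jj) {
        approx(seq_len(n_s), km[, win[jj]], xout = rows + shifts[jj],
               rule = 2, ties = "ordered")$y
      }, numeric(length(rows)))
      m <- rowMeans(vals)
      s2 <- apply(vals, 1, var)
      tot <- tot + max(0, var(m) - mean(s2) / length(win))
      used <- used + 1
    }
    if (used == 0) 0 else tot / used
  }
  grid <- seq(-max_slope_px, max_slope_px, length.out = 81)
  sc <- vapply(grid, score_of, numeric(1))
  i <- which.max(sc)
  # refine around the coarse winner
  fine <- seq(grid[max(1, i - 1)], grid[min(length(grid), i + 1)],
              length.out = 21)
  scf <- vapply(fine, score_of, numeric(1))
  jf <- which.max(scf)
  jr <- parabolic_refine(scf, jf)
  slope <- approx(seq_along(fine), fine, xout = jr, ties = "ordered")$y
  contrast <- max(sc) / (mean(sc) + 1e-12)
  indeterminate <- contrast < 1.2 || max(sc) <= 0
  tibble(flow_um_min = abs(slope) * kymo$pixel_size_um / kymo$dt_s * 60,
         slope_px_per_frame = slope, contrast = contrast,
         indeterminate = indeterminate)
}

#' Cortical retrograde flow of one cell
#'
#' Convenience wrapper for speckle-flow movies of non-adherent (stationary)
#' cells: segments the cell on the membrane channel of `frame`, places the
#' sampling polyline on one lateral cortical arc (contour moved inward onto
#' the actin band), builds the kymograph over all frames, and estimates the
#' flow rate.
#'
#' @param movie a [cell_movie()] with `membrane` and `actin` channels.
#' @param frame frame used to define the mask/polyline.
#' @param direction migration-axis direction (radians); the sampled arc is
#'   the lateral (side) arc where flow runs front-to-back.
#' @param inward_px inward offset from the support contour to the cortical
#'   band (defaults to the membrane-ridge offset of the generator
#'   geometry).
#' @param width_px kymograph averaging width.
#' @param area_range_um2 area filter for the segmentation.
#' @return tibble as [estimate_flow()], plus `arc_px`.
#' @export
cortical_flow <- function(movie, frame = 1, direction = 0, inward_px = NULL,
                          width_px = 5, area_range_um2 = c(38, 60)) {
  seg <- segment_cells(movie_frame(movie, frame, "membrane"),
                       movie$pixel_size_um, area_range_um2)
  if (nrow(seg$metrics) == 0) abort("no cell found in the flow movie")
  lab <- seg$metrics$label[which.max(seg$metrics$area_um2)]
  mask <- seg$labels == lab
  if (is.null(inward_px)) inward_px <- 2
  poly <- resample_polyline(mask_contour(mask), step = 1, closed = TRUE)
  poly <- poly[-nrow(poly), , drop = FALSE]
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  dx <- poly[, 1] - cx; dy <- poly[, 2] - cy
  d <- sqrt(dx^2 + dy^2)
  # lateral arc: contour points whose radial direction is within 60 deg of
  # the +90 deg side normal
  ang <- atan2(dy, dx) - (direction + pi / 2)
  ang <- abs(((ang + pi) %% (2 * pi)) - pi)
  sel <- ang <= pi / 3
  if (sum(sel) < 10) abort("lateral arc too short")
  idx <- which(sel)
  # order the arc monotonically along the contour (single contiguous run
  # assumed for convex shapes; rotate so the run is contiguous)
  br <- which(diff(idx) > 1)
  if (length(br)) idx <- c(idx[(br[1] + 1):length(idx)], idx[seq_len(br[1])])
  arc <- cbind(poly[idx, 1] - inward_px * dx[idx] / d[idx],
               poly[idx, 2] - inward_px * dy[idx] / d[idx])
  # smooth the jagged thresholded contour so the arc-length scale is not
  # inflated by pixelation
  if (nrow(arc) > 7) {
    k <- rep(1 / 5, 5)
    arc <- apply(arc, 2, function(u) {
      sm <- stats::filter(u, k, sides = 2)
      sm[is.na(sm)] <- u[is.na(sm)]
      as.numeric(sm)
    })
  }
  km <- build_kymograph(movie, arc, width_px = width_px, channel = "actin")
  estimate_flow(km) |> mutate(arc_px = nrow(km$data))
}
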