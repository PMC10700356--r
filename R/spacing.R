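# Membrane-to-F-actin spacing along the leading edge.
#
# A profile_stack is a set of two-channel 1-D lines sampled along the inward
# normal of the plasma membrane; after alignment the membrane peak defines
# position 0 and the cell interior lies toward increasing sample index.

new_profile_stack <- function(pm, actin, step_nm, source = "synthetic",
                              aligned = FALSE, pm_peak = NULL,
                              region = NA_character_) {
  stopifnot(all(dim(pm) == dim(actin)))
  structure(list(pm = pm, actin = actin, step_nm = step_nm, source = source,
                 aligned = aligned, pm_peak = pm_peak, region = region),
            class = "profile_stack")
}

#' @export
print.profile_stack <- function(x, ...) {
  cat(sprintf("<profile_stack> %d lines x %d samples @ %.1f nm (%s%s)\n",
              nrow(x$pm), ncol(x$pm), x$step_nm, x$source,
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' Align a profile stack on the plasma-membrane peak
#'
#' Per line, both channels are 0-1 normalized and the membrane peak is
#' located by discrete argmax with 3-point parabolic sub-pixel refinement;
#' the refined peak becomes position 0 of the signed distance axis.
#'
#' @param stack a `profile_stack`.
#' @return the aligned stack.
#' @export
align_profile_stack <- function(stack) {
  if (stack$aligned) return(stack)
  norm01v <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(v * 0)
    (v - r[1]) / diff(r)
  }
  n <- nrow(stack$pm)
  pm <- stack$pm; actin <- stack$actin
  peak <- numeric(n)
  for (i in seq_len(n)) {
    pm[i, ] <- norm01v(pm[i, ])
    actin[i, ] <- norm01v(actin[i, ])
    peak[i] <- parabolic_refine(pm[i, ], which.max(pm[i, ]))
  }
  new_profile_stack(pm, actin, stack$step_nm, stack$source, aligned = TRUE,
                    pm_peak = peak, region = stack$region)
}

#' Trace and straighten the leading-edge membrane band
#'
#' The leading-edge arc is the part of the mask contour whose outward
#' normal lies within 60 degrees of the migration direction. A 30-px-wide
#' band centred on the membrane-channel ridge is resampled along the inward
#' normal of the arc (bilinear), giving a rectangular two-channel band with
#' the membrane ridge running horizontally near the middle row and the cell
#' interior toward larger row indices.
#'
#' @param pm_image,actin_image numeric matrices (same size).
#' @param mask logical cell mask.
#' @param direction arc centre direction (radians); the migration direction
#'   for the leading edge.
#' @param band_width_px band width along the normal.
#' @param arc_halfwidth_deg angular half-width of the selected arc (contour
#'   points whose outward normal is within this angle of `direction`).
#' @return list with `pm` and `actin` band matrices (band_width x arc
#'   length) and `arc_length_px`.
#' @export
trace_and_straighten_edge <- function(pm_image, actin_image, mask, direction,
                                      band_width_px = 30,
                                      arc_halfwidth_deg = 60) {
  poly <- resample_polyline(mask_contour(mask), step = 1, closed = TRUE)
  poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  # outward normal from the local tangent, oriented away from the centroid
  nxt <- poly[c(2:n, 1), ]; prv <- poly[c(n, 1:(n - 1)), ]
  tx <- nxt[, 1] - prv[, 1]; ty <- nxt[, 2] - prv[, 2]
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl; nyv <- tx / tl
  flipn <- (nx * (poly[, 1] - cx) + nyv * (poly[, 2] - cy)) < 0
  nx[flipn] <- -nx[flipn]; nyv[flipn] <- -nyv[flipn]
  ang <- acos(pmin(1, pmax(-1, nx * cos(direction) + nyv * sin(direction))))
  sel <- ang <= arc_halfwidth_deg / 180 * pi
  if (sum(sel) < 20) abort("leading-edge arc shorter than 20 px")
  # take the longest contiguous run (wrapping) of selected contour points
  runs <- rle(sel[c(seq_len(n), seq_len(n))])
  ends <- cumsum(runs$lengths)
  cand <- which(runs$values & runs$lengths == max(runs$lengths[runs$values]))[1]
  i1 <- ends[cand] - runs$lengths[cand] + 1
  idx <- ((i1:(i1 + min(runs$lengths[cand], n) - 1)) - 1) %% n + 1
  arc <- poly[idx, , drop = FALSE]
  anx <- nx[idx]; any_ <- nyv[idx]
  # locate the membrane ridge inward of the support contour, then smooth
  probe <- 0:8
  ridge_off <- vapply(seq_len(nrow(arc)), function(i) {
    v <- bilinear_sample(pm_image, arc[i, 1] - anx[i] * probe,
                         arc[i, 2] - any_[i] * probe)
    parabolic_refine(v, which.max(v)) - 1
  }, numeric(1))
  ridge_off <- stats::filter(ridge_off, rep(1 / 9, 9), sides = 2,
                             circular = FALSE)
  ridge_off[is.na(ridge_off)] <- mean(ridge_off, na.rm = TRUE)
  half <- band_width_px / 2
  offs <- seq(-half + 0.5, half - 0.5, by = 1)   # row 15.5 = ridge
  sample_band <- function(img) {
    out <- matrix(0, band_width_px, nrow(arc))
    for (i in seq_len(nrow(arc))) {
      d <- ridge_off[i] + offs
      out[, i] <- bilinear_sample(img, arc[i, 1] - anx[i] * d,
                                  arc[i, 2] - any_[i] * d)
    }
    out
  }
  list(pm = sample_band(pm_image), actin = sample_band(actin_image),
       arc_length_px = nrow(arc))
}

#' Perpendicular line profiles across a straightened edge band
#'
#' Overlapping lines perpendicular to the membrane: each line averages a
#' `line_width_px`-wide window of arc positions, advancing by `step_px`
#' (50% overlap by default). Lines are 0-1 normalized and aligned on the
#' membrane peak with parabolic sub-pixel refinement.
#'
#' @param band output of [trace_and_straighten_edge()].
#' @param line_width_px averaging width along the edge.
#' @param step_px advance between consecutive lines.
#' @param pixel_size_um pixel size (um/px), sets the distance scale.
#' @param region optional region label (`"leading edge"`, `"side"`).
#' @return an aligned `profile_stack` with
#'   `floor((W - line_width_px) / step_px) + 1` lines.
#' @export
perpendicular_profiles <- function(band, line_width_px = 20, step_px = 10,
                                   pixel_size_um, region = NA_character_) {
  w <- ncol(band$pm)
  if (w < line_width_px) abort("band narrower than `line_width_px`")
  starts <- seq(1, w - line_width_px + 1, by = step_px)
  pm <- t(vapply(starts, function(s) {
    rowMeans(band$pm[, s:(s + line_width_px - 1), drop = FALSE])
  }, numeric(nrow(band$pm))))
  actin <- t(vapply(starts, function(s) {
    rowMeans(band$actin[, s:(s + line_width_px - 1), drop = FALSE])
  }, numeric(nrow(band$actin))))
  align_profile_stack(new_profile_stack(pm, actin,
                                        step_nm = pixel_size_um * 1000,
                                        source = "straightened",
                                        region = region))
}

#' Distance from the membrane peak to the nearest-interior F-actin peak
#'
#' Per aligned line, the actin peak is the highest actin sample in the
#' interior-side window `(0, window_nm]` of the membrane peak, refined to
#' sub-pixel precision with a 3-point parabola; the per-cell (per-stack)
#' value is the mean over lines. Lines with no interior samples inside the
#' window are skipped with a flag.
#'
#' @param stack a `profile_stack` (aligned automatically if not).
#' @param window_nm search window on the interior side (nm).
#' @return a `spacing_result`: list with `per_line` (tibble: `line`,
#'   `distance_nm`, `skipped`), `mean_nm`, `n_lines`, `region`, `step_nm`.
#' @export
actin_peak_distance <- function(stack, window_nm = 400) {
  stack <- align_profile_stack(stack)
  n <- nrow(stack$actin)
  res <- lapply(seq_len(n), function(i) {
    pos <- (seq_len(ncol(stack$actin)) - stack$pm_peak[i]) * stack$step_nm
    cand <- which(pos > 0 & pos <= window_nm)
    if (!length(cand)) {
      return(tibble(line = i, distance_nm = NA_real_, skipped = TRUE))
    }
    j <- cand[which.max(stack$actin[i, cand])]
    # parabolic refinement with a one-sample reach: an actin peak coincident
    # with (or just outside) the membrane peak sits at the window edge and
    # must be allowed to refine back toward zero
    v <- stack$actin[i, ]
    jr <- j
    if (j > 1 && j < length(v)) {
      den <- v[j - 1] - 2 * v[j] + v[j + 1]
      if (is.finite(den) && den != 0) {
        jr <- j + max(-1, min(1, 0.5 * (v[j - 1] - v[j + 1]) / den))
      }
    }
    d <- max(0, (jr - stack$pm_peak[i]) * stack$step_nm)
    tibble(line = i, distance_nm = d, skipped = FALSE)
  }) |> bind_rows()
  if (all(res$skipped)) abort("no line has interior samples within the window")
  structure(list(per_line = res,
                 mean_nm = mean(res$distance_nm[!res$skipped]),
                 n_lines = sum(!res$skipped), region = stack$region,
                 step_nm = stack$step_nm),
            class = "spacing_result")
}

#' @export
print.spacing_result <- function(x, ...) {
  cat(sprintf("<spacing_result> mean %.1f nm over %d lines%s\n", x$mean_nm,
              x$n_lines,
              if (!is.na(x$region)) paste0(" (", x$region, ")") else ""))
  invisible(x)
}

#' @export
tidy.spacing_result <- function(x, ...) x$per_line

#' @export
glance.spacing_result <- function(x, ...) {
  tibble(mean_nm = x$mean_nm, n_lines = x$n_lines, region = x$region,
         step_nm = x$step_nm)
}

#' Membrane-actin spacing of one cell from a movie frame
#'
#' Convenience wrapper: segments the chosen frame, straightens the leading
#' edge (or a side arc) of the cell nearest `which_cell`'s ground-truth
#' position, and measures the actin peak distance.
#'
#' @param movie a [cell_movie()] with `membrane` and `actin` channels.
#' @param mask logical cell mask for the chosen frame.
#' @param direction migration direction (radians).
#' @param frame frame index.
#' @param region `"leading edge"` (normals within 60 deg of `direction`) or
#'   `"side"` (normals within 60 deg of the perpendicular).
#' @param window_nm actin search window (nm).
#' @return a `spacing_result`.
#' @export
cell_edge_spacing <- function(movie, mask, direction, frame = 1,
                              region = c("leading edge", "side"),
                              window_nm = 400) {
  region <- match.arg(region)
  # the side arc is centred 105 deg off the migration direction with a
  # 30 deg half-width, clear of the leading-edge transition zone
  dir_use <- if (region == "side") direction + 105 / 180 * pi else direction
  hw <- if (region == "side") 30 else 60
  band <- trace_and_straighten_edge(movie_frame(movie, frame, "membrane"),
                                    movie_frame(movie, frame, "actin"),
                                    mask, dir_use, arc_halfwidth_deg = hw)
  stk <- perpendicular_profiles(band, pixel_size_um = movie$pixel_size_um,
                                region = region)
  actin_peak_distance(stk, window_nm = window_nm)
}

#' Correlation between membrane-actin spacing and migration speed
#'
#' Pearson correlation with a two-sided t-test (n - 2 df) and the
#' least-squares line, the analysis used to relate leading-edge spacing to
#' cell speed.
#'
#' @param data data frame of per-cell values.
#' @param spacing,speed columns of `data` (tidy-eval) holding the per-cell
#'   spacing and speed.
#' @return tibble: `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
spacing_speed_correlation <- function(data, spacing, speed) {
  x <- eval_tidy(enquo(speed), data)
  y <- eval_tidy(enquo(spacing), data)
  pearson_fit(x, y)
}

# shared Pearson machinery (also behind pearson_test)
pearson_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need >= 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  slope <- r * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble(r = r, p_value = p, slope = slope, intercept = intercept, n = n)
}
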