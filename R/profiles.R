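# Spatial distribution of fluorescent reporters along and around migrating
# cells: aligned mean projections, 12-bin length profiles, LE/TE anchoring,
# perimeter polarization and MPAct/CaaX ratios.

#' 12-bin intensity profile along the cell axis
#'
#' Construct or manipulate binned length profiles: the cell length (along
#' the migration axis through the mask centroid) is divided into `n_bins`
#' equal-length bins, and each bin value is the mean intensity over all mask
#' pixels whose axial coordinate falls in the bin (full cell width). Bin 1
#' is the leading edge when `oriented_le_first`.
#'
#' @param values numeric vector of bin means.
#' @param oriented_le_first is bin 1 the leading edge?
#' @param normalization `"raw"` or `"unit01"`.
#' @param degenerate flag set when a constant profile was 0-1 normalized.
#' @return a `binned_profile`.
#' @export
binned_profile <- function(values, oriented_le_first = TRUE,
                           normalization = "raw", degenerate = FALSE) {
  structure(list(values = as.numeric(values),
                 oriented_le_first = oriented_le_first,
                 normalization = match.arg(normalization,
                                           c("raw", "unit01", "unit_max")),
                 degenerate = degenerate),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("<binned_profile> %d bins (%s%s)\n", length(x$values),
              x$normalization, if (x$degenerate) ", degenerate" else ""))
  print(round(x$values, 4))
  invisible(x)
}

#' @rdname binned_profile
#' @param image numeric matrix.
#' @param mask logical matrix, same size (non-empty).
#' @param direction migration direction (radians, image axes).
#' @param n_bins number of axial bins.
#' @export
length_profile <- function(image, mask, direction, n_bins = 12) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("empty mask")
  cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
  ax <- (idx[, 2] - cx) * cos(direction) + (idx[, 1] - cy) * sin(direction)
  rng <- range(ax)
  if (diff(rng) < n_bins) {
    abort(sprintf("mask shorter than %d px along the axis", n_bins))
  }
  # bin 1 = leading edge (largest axial coordinate)
  edges <- seq(rng[2], rng[1], length.out = n_bins + 1)
  bin <- pmin(n_bins, pmax(1, findInterval(-ax, -edges, rightmost.closed = TRUE)))
  vals <- image[idx]
  means <- vapply(seq_len(n_bins), function(b) mean(vals[bin == b]), numeric(1))
  binned_profile(means, oriented_le_first = TRUE)
}

#' Normalize a profile to the 0-1 range
#'
#' `(v - min) / (max - min)` per profile; a constant profile maps to zeros
#' with the degenerate flag set. Idempotent.
#'
#' @param profile a [binned_profile()].
#' @return a unit01-normalized `binned_profile`.
#' @export
normalize01 <- function(profile) {
  v <- profile$values
  rng <- range(v)
  if (diff(rng) == 0) {
    return(binned_profile(rep(0, length(v)), profile$oriented_le_first,
                          "unit01", degenerate = TRUE))
  }
  binned_profile((v - rng[1]) / diff(rng), profile$oriented_le_first, "unit01",
                 degenerate = FALSE)
}

#' Normalize a profile by its maximum
#'
#' `v / max(v)` per profile (the per-fluorophore normalization used for
#' ratio imaging, where dividing two max-normalized channels leaves their
#' true ratio shape intact). Idempotent; a constant profile of zeros gets
#' the degenerate flag.
#'
#' @param profile a [binned_profile()].
#' @return a max-normalized `binned_profile` (normalization `"unit_max"`).
#' @export
normalize_max <- function(profile) {
  v <- profile$values
  mx <- max(v)
  if (mx <= 0) {
    return(binned_profile(rep(0, length(v)), profile$oriented_le_first,
                          "unit_max", degenerate = TRUE))
  }
  binned_profile(v / mx, profile$oriented_le_first, "unit_max",
                 degenerate = FALSE)
}

#' Align and mean-project cell crops in the migration direction
#'
#' Each crop is rotated so its migration direction points toward +x,
#' cropped/padded about the mask/image centre to a fixed ROI box, and the
#' result averaged pixel-wise across cells (mean intensity projection).
#'
#' @param cell_crops list of numeric matrices (>= 1).
#' @param directions migration direction (radians) per crop.
#' @param roi_um ROI box as `c(length, height)` in um (a single value uses
#'   a 2:1 box).
#' @param pixel_size_um pixel size (um/px).
#' @return the mean-projected ROI matrix.
#' @export
align_and_project <- function(cell_crops, directions, roi_um,
                              pixel_size_um) {
  if (length(cell_crops) == 0) abort("no crops supplied")
  if (length(directions) != length(cell_crops)) {
    abort("`directions` must match `cell_crops`")
  }
  if (length(roi_um) == 1) roi_um <- c(roi_um, roi_um / 2)
  nxo <- round(roi_um[1] / pixel_size_um)
  nyo <- round(roi_um[2] / pixel_size_um)
  acc <- matrix(0, nyo, nxo)
  for (i in seq_along(cell_crops)) {
    img <- cell_crops[[i]]
    rot <- rotate_image(img, directions[i])
    cy <- (nrow(rot) + 1) / 2; cx <- (ncol(rot) + 1) / 2
    g <- expand.grid(y = seq_len(nyo), x = seq_len(nxo))  # row index fastest
    xs <- cx + (g$x - (nxo + 1) / 2)
    ys <- cy + (g$y - (nyo + 1) / 2)
    acc <- acc + matrix(bilinear_sample(rot, xs, ys), nyo, nxo)
  }
  acc / length(cell_crops)
}

#' Orient profiles using leading/trailing edge markers
#'
#' CDC42 marks the leading edge and CD44 the trailing edge: all profiles
#' are flipped, if needed, so the CDC42 peak bin precedes the CD44 peak
#' bin. When the two marker peaks fall within 2 bins of each other the
#' orientation is ambiguous: profiles are returned unchanged with a
#' conflict flag.
#'
#' @param profiles named list of [binned_profile()]s including `CDC42` and
#'   `CD44`.
#' @return list with `profiles` (oriented), `flipped`, `conflict`.
#' @export
anchor_le_te <- function(profiles) {
  if (!all(c("CDC42", "CD44") %in% names(profiles))) {
    abort("`profiles` must include CDC42 and CD44")
  }
  i_le <- which.max(profiles$CDC42$values)
  i_te <- which.max(profiles$CD44$values)
  if (abs(i_le - i_te) <= 2) {
    return(list(profiles = profiles, flipped = FALSE, conflict = TRUE))
  }
  flip <- i_le > i_te
  if (flip) {
    profiles <- lapply(profiles, function(p) {
      binned_profile(rev(p$values), p$oriented_le_first, p$normalization,
                     p$degenerate)
    })
  }
  list(profiles = profiles, flipped = flip, conflict = FALSE)
}

#' Sample fluorescence along the cell perimeter
#'
#' The mask contour (marching squares) is resampled to ~1-px arc spacing,
#' optionally moved inward toward the centroid (to sit on the membrane
#' ridge rather than the support edge), and intensities are read by
#' bilinear interpolation.
#'
#' @param image numeric matrix.
#' @param mask logical matrix.
#' @param offset_px inward offset from the mask contour (px).
#' @return numeric vector of arc-ordered intensities (closed contour).
#' @export
perimeter_profile <- function(image, mask, offset_px = 0) {
  poly <- mask_contour(mask)
  rs <- resample_polyline(poly, step = 1, closed = TRUE)
  rs <- rs[-nrow(rs), , drop = FALSE]
  if (offset_px != 0) {
    cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
    dx <- rs[, 1] - cx; dy <- rs[, 2] - cy
    d <- sqrt(dx^2 + dy^2)
    rs <- cbind(rs[, 1] - offset_px * dx / d, rs[, 2] - offset_px * dy / d)
  }
  bilinear_sample(image, rs[, 1], rs[, 2])
}

#' Perimeter polarization ratio
#'
#' Fluorescence in the 25% of the perimeter centred on the maximum,
#' divided by the total perimeter fluorescence. 0.25 for a uniform
#' contour, 1 for a single bright point; invariant to the contour start
#' point and to intensity scaling.
#'
#' @param contour_intensity arc-ordered non-negative intensities along a
#'   closed contour (>= 8 samples).
#' @return ratio in (0, 1].
#' @export
perimeter_polarization <- function(contour_intensity) {
  v <- as.numeric(contour_intensity)
  n <- length(v)
  if (n < 8) abort("need >= 8 perimeter samples")
  if (any(v < 0)) abort("intensities must be >= 0")
  tot <- sum(v)
  if (tot <= 0) abort("total perimeter fluorescence is zero")
  w <- ceiling(0.25 * n)
  i0 <- which.max(v)                       # ties -> lowest index
  off <- seq_len(w) - 1 - floor((w - 1) / 2)
  idx <- ((i0 - 1 + off) %% n) + 1
  sum(v[idx]) / tot
}

#' Membrane-proximal actin polarity from MPAct/CaaX profiles
#'
#' Each fluorophore's profile is normalized by its own maximum (see
#' [normalize_max()]; applied internally, so raw profiles are accepted),
#' the MPAct profile is divided by the CaaX profile bin-wise, and polarity
#' is the mean of the front `k` ratio bins over the mean of the back `k`
#' ratio bins. Bins where the normalized CaaX value falls below `guard`
#' are excluded from the ratio (near-zero denominators carry no membrane
#' signal).
#'
#' @param mpact_profile,caax_profile LE-first [binned_profile()]s (raw or
#'   max-normalized).
#' @param k number of front/back bins in the polarity summary.
#' @param guard minimum normalized CaaX value for a usable ratio bin.
#' @return list with `ratio` (per-bin ratios, `NA` where guarded) and
#'   `polarity` (front-over-back scalar).
#' @export
mpact_polarity <- function(mpact_profile, caax_profile, k = 3, guard = 0.05) {
  mpact_profile <- normalize_max(mpact_profile)
  caax_profile <- normalize_max(caax_profile)
  m <- mpact_profile$values; cx <- caax_profile$values
  if (length(m) != length(cx)) abort("profiles must have the same bins")
  n <- length(m)
  ratio <- ifelse(cx >= guard, m / cx, NA_real_)
  front <- ratio[seq_len(k)]
  back <- ratio[seq.int(n - k + 1, n)]
  fb <- mean(front, na.rm = TRUE)
  bb <- mean(back, na.rm = TRUE)
  if (!is.finite(bb) || bb == 0) abort("back-bin ratio mean is zero or undefined")
  if (!is.finite(fb)) abort("front-bin ratio mean undefined (all bins guarded)")
  list(ratio = binned_profile(ratio, TRUE, "raw"), polarity = fb / bb)
}
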