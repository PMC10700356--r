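# Segmentation, track linking, exclusion rules and speed/shape metrics.

#' Triangle auto-threshold
#'
#' Geometric triangle construction on a 256-bin histogram: a line is drawn
#' from the histogram peak to the far end of the longer tail, and the
#' threshold is the bin maximizing the perpendicular distance between the
#' histogram and that line.
#'
#' @param image numeric matrix (or vector) of intensities; must not be
#'   constant.
#' @return threshold intensity; pixels strictly above it are foreground.
#' @export
triangle_threshold <- function(image) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) abort("constant image: no threshold exists")
  nb <- 256
  brk <- seq(rng[1], rng[2], length.out = nb + 1)
  h <- tabulate(pmin(nb, findInterval(v, brk, rightmost.closed = TRUE)), nb)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- min(nz); hi <- max(nz)
  # pick the longer tail; mirror so the tail always runs to the right
  flip <- (peak - lo) > (hi - peak)
  if (flip) {
    h <- rev(h)
    peak <- nb - peak + 1
    hi <- nb - lo + 1
  }
  if (hi <= peak) return(mean(rng))   # degenerate single-bin tail
  b <- peak:hi
  # signed distance of (b, h[b]) below the chord from (peak, h[peak]) to (hi, h[hi])
  t <- (b - peak) / (hi - peak)
  chord <- h[peak] + t * (h[hi] - h[peak])
  ibest <- b[which.max(chord - h[b])]
  if (flip) ibest <- nb - ibest + 1
  brk[ibest]   # lower edge of the chosen bin
}

#' Shape metrics of a binary mask
#'
#' Area from the pixel count, perimeter from the marching-squares contour
#' polygon, circularity `4*pi*A/P^2` (1 for a circle, ~pi/4 for a square).
#'
#' @param mask logical matrix.
#' @param pixel_size_um pixel size (um/px).
#' @return tibble with `area_um2`, `perimeter_um`, `circularity`.
#' @export
shape_metrics <- function(mask, pixel_size_um) {
  a_px <- sum(mask)
  if (a_px == 0) abort("empty mask")
  per_px <- poly_perimeter(smooth_closed_poly(mask_contour(mask)))
  area <- a_px * pixel_size_um^2
  perim <- per_px * pixel_size_um
  tibble(area_um2 = area, perimeter_um = perim,
         circularity = 4 * pi * area / perim^2)
}

#' Segment cells in one frame
#'
#' Triangle threshold, radius-1 disc binary opening, 8-connected components,
#' and an inclusive area filter (default 38-60 um^2, the size window for
#' naive T cells).
#'
#' @param frame 2-D numeric matrix.
#' @param pixel_size_um pixel size (um/px).
#' @param area_range_um2 inclusive `[min, max]` area filter.
#' @return list with `labels` (integer matrix; only retained cells keep a
#'   label) and `metrics` (tibble: `label`, `x_um`, `y_um`, `area_um2`,
#'   `perimeter_um`, `circularity`).
#' @export
segment_cells <- function(frame, pixel_size_um, area_range_um2 = c(38, 60)) {
  empty <- list(labels = matrix(0L, nrow(frame), ncol(frame)),
                metrics = tibble(label = integer(), x_um = numeric(),
                                 y_um = numeric(), area_um2 = numeric(),
                                 perimeter_um = numeric(),
                                 circularity = numeric()))
  if (diff(range(frame)) == 0) return(empty)
  thr <- triangle_threshold(frame)
  bw <- frame > thr
  if (!any(bw)) return(empty)
  brush <- EBImage::makeBrush(3, shape = "disc")
  op <- EBImage::opening(EBImage::Image(bw * 1), brush)
  lab <- labels_to_8conn(EBImage::imageData(EBImage::bwlabel(op)))
  k <- max(lab)
  if (k == 0) return(empty)
  rows <- list()
  keep <- integer(0)
  for (l in seq_len(k)) {
    m <- lab == l
    a <- sum(m) * pixel_size_um^2
    if (a < area_range_um2[1] || a > area_range_um2[2]) next
    sm <- shape_metrics(m, pixel_size_um)
    idx <- which(m, arr.ind = TRUE)
    rows[[length(rows) + 1]] <- tibble(
      label = l,
      x_um = (mean(idx[, 2]) - 1) * pixel_size_um,
      y_um = (mean(idx[, 1]) - 1) * pixel_size_um,
      area_um2 = sm$area_um2, perimeter_um = sm$perimeter_um,
      circularity = sm$circularity)
    keep <- c(keep, l)
  }
  lab[!(lab %in% keep)] <- 0L
  list(labels = lab,
       metrics = if (length(rows)) bind_rows(rows) else empty$metrics)
}

# Dead-cell call: mean viability-channel intensity inside the mask exceeds
# the triangle threshold of the viability channel. The threshold is floored
# at a robust background bound (median + 5 MAD) so that a channel containing
# only background noise - no dead cells at all - cannot produce spurious
# positives (a symmetric noise histogram puts the triangle threshold just
# beside the noise peak).
flag_dead <- function(labels, metrics, viability) {
  if (nrow(metrics) == 0) return(metrics |> mutate(viable = logical(0)))
  if (diff(range(viability)) == 0) {
    return(metrics |> mutate(viable = FALSE))
  }
  thr <- max(triangle_threshold(viability),
             median(viability) + 5 * stats::mad(viability))
  metrics |> mutate(
    viable = vapply(.data$label, function(l) {
      mean(viability[labels == l]) > thr
    }, logical(1)))
}

#' Detect cells in every frame of a movie
#'
#' Runs [segment_cells()] per frame on the segmentation channel and flags
#' propidium-iodide-style dead cells from the viability channel.
#'
#' @param movie a [cell_movie()] time series.
#' @param channel segmentation channel (name or index).
#' @param viability_channel viability channel, or `NULL` to skip dead-cell
#'   flagging.
#' @param area_range_um2 inclusive area filter passed to [segment_cells()].
#' @return tibble of detections: `frame`, `x_um`, `y_um`, shape metrics,
#'   `viable`.
#' @export
detect_cells <- function(movie, channel = "membrane",
                         viability_channel = "viability",
                         area_range_um2 = c(38, 60)) {
  stopifnot(movie$axis_kind == "time")
  n_t <- dim(movie$data)[1]
  out <- lapply(seq_len(n_t), function(t) {
    seg <- segment_cells(movie_frame(movie, t, channel), movie$pixel_size_um,
                         area_range_um2)
    m <- if (!is.null(viability_channel)) {
      flag_dead(seg$labels, seg$metrics,
                movie_frame(movie, t, viability_channel))
    } else {
      seg$metrics |> mutate(viable = FALSE)
    }
    m |> mutate(frame = t)
  })
  bind_rows(out) |> select("frame", dplyr::everything())
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour frame-to-frame linking under a maximum
#' displacement; unmatched detections start new tracks; no gap closing.
#' When `max_disp_um` is `NULL` it is set to 3x the median per-frame
#' displacement estimated from an unconstrained first pass.
#'
#' @param detections tibble with `frame`, `x_um`, `y_um` and optionally
#'   `viable` plus any per-detection columns to carry through.
#' @param max_disp_um maximum link displacement (um), or `NULL` to
#'   auto-estimate.
#' @return track tibble: the input rows plus `track_id`.
#' @export
link_tracks <- function(detections, max_disp_um = NULL) {
  if (nrow(detections) == 0) {
    return(detections |> mutate(track_id = integer(0)))
  }
  if (is.null(max_disp_um)) {
    first <- link_tracks(detections, max_disp_um = Inf)
    d <- first |>
      arrange(.data$track_id, .data$frame) |>
      group_by(.data$track_id) |>
      summarise(step = list(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
                .groups = "drop")
    steps <- unlist(d$step)
    max_disp_um <- if (length(steps) && median(steps) > 0) 3 * median(steps) else Inf
  }
  det <- detections |> arrange(.data$frame) |> mutate(.row = dplyr::row_number())
  frames <- sort(unique(det$frame))
  det$track_id <- NA_integer_
  next_id <- 1L
  prev <- det[det$frame == frames[1], ]
  det$track_id[prev$.row] <- seq_len(nrow(prev))
  next_id <- nrow(prev) + 1L
  for (fi in seq_along(frames)[-1]) {
    cur <- det[det$frame == frames[fi], ]
    prev <- det[det$frame == frames[fi - 1], ]
    if (nrow(prev) && nrow(cur) && frames[fi] == frames[fi - 1] + 1) {
      dm <- outer(seq_len(nrow(prev)), seq_len(nrow(cur)),
                  Vectorize(function(i, j) {
                    sqrt((prev$x_um[i] - cur$x_um[j])^2 +
                         (prev$y_um[i] - cur$y_um[j])^2)
                  }))
      # greedy mutual NN: repeatedly take the globally smallest admissible
      # pair (ties by smaller distance, then smaller indices)
      repeat {
        k <- which.min(dm)
        if (!length(k) || !is.finite(dm[k]) || dm[k] > max_disp_um) break
        i <- (k - 1) %% nrow(dm) + 1
        j <- (k - 1) %/% nrow(dm) + 1
        det$track_id[cur$.row[j]] <- det$track_id[prev$.row[i]]
        dm[i, ] <- Inf; dm[, j] <- Inf
      }
    }
    new <- cur$.row[is.na(det$track_id[cur$.row])]
    if (length(new)) {
      det$track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
  }
  det |> select(-".row") |> arrange(.data$track_id, .data$frame)
}

#' Apply the track exclusion rules
#'
#' Removes viability-positive (dead-cell) tracks and tracks observed for
#' strictly less than `min_fraction` of the video length (1/2 for the
#' under-agarose assay, 1/3 for collagen); a track of exactly the minimum
#' length is kept.
#'
#' @param tracks track tibble with `track_id`, `frame`, and optionally
#'   `viable`.
#' @param n_frames total video length in frames.
#' @param min_fraction minimum retained fraction of the video length.
#' @return filtered track tibble.
#' @export
filter_tracks <- function(tracks, n_frames, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be in (0, 1]")
  }
  if (nrow(tracks) == 0) return(tracks)
  has_v <- "viable" %in% names(tracks)
  keep <- tracks |>
    group_by(.data$track_id) |>
    summarise(len = dplyr::n(),
              dead = if (has_v) any(.data$viable) else FALSE,
              .groups = "drop") |>
    filter(.data$len >= min_fraction * n_frames, !.data$dead)
  tracks |> filter(.data$track_id %in% keep$track_id)
}

#' Mean track speed
#'
#' Path length divided by elapsed time (the TrackMate-style mean speed), in
#' um/min.
#'
#' @param track tibble with `frame`, `x_um`, `y_um` for a single track
#'   (>= 2 points).
#' @param dt_s frame interval (s).
#' @return speed in um/min.
#' @export
track_speed <- function(track, dt_s) {
  if (nrow(track) < 2) abort("track must have at least 2 points")
  tr <- track |> arrange(.data$frame)
  path <- sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2))
  mins <- (max(tr$frame) - min(tr$frame)) * dt_s / 60
  path / mins
}

#' Per-track speeds for a whole track table
#'
#' @param tracks track tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param dt_s frame interval (s).
#' @return tibble: `track_id`, `n_frames`, `speed_um_min`.
#' @export
track_speeds <- function(tracks, dt_s) {
  tracks |>
    group_by(.data$track_id) |>
    summarise(n_frames = dplyr::n(),
              speed_um_min = track_speed(dplyr::pick(dplyr::everything()), dt_s),
              .groups = "drop")
}
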