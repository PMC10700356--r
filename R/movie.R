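#' Multi-channel movie / z-stack container
#'
#' A `cell_movie` holds a 4-D intensity array ordered (time-or-z, channel,
#' y, x) together with the acquisition metadata every downstream stage needs:
#' physical pixel size, the frame interval (time series) or slice spacing
#' (z-stack), and named channels.
#'
#' @param data 4-D numeric array, dimensions (n_frames_or_slices, n_channels,
#'   ny, nx).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param dt_s frame interval in seconds (time series only).
#' @param dz_um z-slice spacing in micrometres (z-stacks only). Exactly one
#'   of `dt_s` / `dz_um` must be given.
#' @param channel_names character vector naming the channel axis.
#' @param axis_kind `"time"` or `"z"`; inferred from whichever of
#'   `dt_s`/`dz_um` is set.
#' @return An object of class `cell_movie`.
#' @export
cell_movie <- function(data, pixel_size_um, dt_s = NULL, dz_um = NULL,
                       channel_names, axis_kind = NULL) {
  if (length(dim(data)) != 4) abort("`data` must be a 4-D array (t/z, c, y, x)")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a positive number")
  }
  if (is.null(dt_s) == is.null(dz_um)) {
    abort("exactly one of `dt_s` and `dz_um` must be supplied")
  }
  if (is.null(axis_kind)) axis_kind <- if (is.null(dz_um)) "time" else "z"
  axis_kind <- match.arg(axis_kind, c("time", "z"))
  if ((axis_kind == "time") != is.null(dz_um)) {
    abort("`axis_kind` inconsistent with dt_s/dz_um")
  }
  if (dim(data)[2] != length(channel_names)) {
    abort("channel axis length does not match `channel_names`")
  }
  structure(
    list(data = data, pixel_size_um = pixel_size_um, dt_s = dt_s,
         dz_um = dz_um, channel_names = channel_names, axis_kind = axis_kind),
    class = "cell_movie"
  )
}

#' @export
print.cell_movie <- function(x, ...) {
  d <- dim(x$data)
  step <- if (x$axis_kind == "time") paste0(x$dt_s, " s") else paste0(x$dz_um, " um")
  cat(sprintf(
    "<cell_movie> %d %s x %d channel(s) x %d x %d px @ %.4f um/px, step %s\n",
    d[1], if (x$axis_kind == "time") "frame(s)" else "slice(s)",
    d[2], d[3], d[4], x$pixel_size_um, step))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of one frame as a matrix
#'
#' @param movie a [cell_movie()].
#' @param frame frame (or z-slice) index.
#' @param channel channel name or index.
#' @return numeric matrix `[y, x]`.
#' @export
movie_frame <- function(movie, frame = 1, channel = 1) {
  if (is.character(channel)) {
    channel <- match(channel, movie$channel_names)
    if (is.na(channel)) abort("unknown channel name")
  }
  movie$data[frame, channel, , ]
}

#' Write / read a movie as multi-page TIFF with a JSON metadata side-car
#'
#' Pages are stored in (t, c) order, 16-bit when the data are integral counts
#' in `[0, 65535]` (a lossless round trip), 32-bit float otherwise.
#' Acquisition metadata (pixel size, frame interval or z spacing, channel
#' names, axis kind) is written to `<path>.meta.json`. On read, metadata
#' missing from the side-car must be supplied explicitly or an error is
#' raised.
#'
#' @param movie a [cell_movie()].
#' @param path output TIFF path.
#' @return `write_movie` returns `path` invisibly; `read_movie` a
#'   [cell_movie()].
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "cell_movie"))
  d <- dim(movie$data)
  pages <- vector("list", d[1] * d[2])
  k <- 1
  integral <- all(movie$data == round(movie$data)) &&
    min(movie$data) >= 0 && max(movie$data) <= 65535
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      m <- movie$data[t, ch, , ]
      pages[[k]] <- if (integral) m / 65535 else m
      k <- k + 1
    }
  }
  if (integral) {
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "LZW")
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "LZW")
  }
  meta <- list(
    axes = "TCYX", size_t = d[1], size_c = d[2], size_y = d[3], size_x = d[4],
    pixel_size_um = movie$pixel_size_um, dt_s = movie$dt_s,
    dz_um = movie$dz_um, channel_names = movie$channel_names,
    axis_kind = movie$axis_kind, scale = if (integral) 65535 else 1
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @param path TIFF path written by [write_movie()] (or any grayscale
#'   multi-page TIFF).
#' @param pixel_size_um,dt_s,dz_um,channel_names overrides used when the
#'   side-car is absent or incomplete.
#' @rdname write_movie
#' @export
read_movie <- function(path, pixel_size_um = NULL, dt_s = NULL, dz_um = NULL,
                       channel_names = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(pixel_size_um)) {
    abort("pixel size metadata absent; supply `pixel_size_um` explicitly")
  }
  dt_s <- dt_s %||% meta$dt_s
  dz_um <- dz_um %||% meta$dz_um
  n_c <- if (!is.null(channel_names)) length(channel_names)
         else if (!is.null(meta$size_c)) meta$size_c else 1
  channel_names <- channel_names %||%
    (if (!is.null(meta$channel_names)) unlist(meta$channel_names)
     else paste0("ch", seq_len(n_c)))
  n_t <- length(pages) / n_c
  if (n_t != round(n_t)) abort("page count is not a multiple of channel count")
  scale <- meta$scale %||% 1
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(n_t, n_c, ny, nx))
  k <- 1
  for (t in seq_len(n_t)) {
    for (ch in seq_len(n_c)) {
      arr[t, ch, , ] <- round(pages[[k]] * scale, 6)
      k <- k + 1
    }
  }
  if (scale == 65535) arr <- round(arr)
  cell_movie(arr, pixel_size_um = as.numeric(pixel_size_um),
             dt_s = if (is.null(dt_s)) NULL else as.numeric(dt_s),
             dz_um = if (is.null(dz_um)) NULL else as.numeric(dz_um),
             channel_names = channel_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write track tables
#'
#' Track tables are plain CSV with columns
#' `track_id,frame,x_um,y_um,viable`. `read_tracks` validates that frames
#' are strictly increasing within each track and that coordinates are
#' finite, reporting offending rows by line number.
#'
#' @param path CSV path.
#' @return a tibble with one row per (track, frame) detection.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_um", "y_um", "viable")
  if (!all(need %in% names(df))) {
    abort(paste0("track CSV must have columns: ", paste(need, collapse = ",")))
  }
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad)) {
    abort(paste0("non-finite coordinates at line(s) ",
                 paste(bad + 1, collapse = ", ")))
  }
  df <- as_tibble(df)
  # frames must be strictly increasing in file order within each track
  nonmono <- unlist(lapply(split(seq_len(nrow(df)), df$track_id), function(i) {
    f <- df$frame[i]
    i[c(FALSE, diff(f) <= 0)]
  }))
  if (length(nonmono)) {
    abort(paste0("frames not strictly increasing within track at line(s) ",
                 paste(sort(nonmono + 1), collapse = ", ")))
  }
  df$viable <- as.logical(df$viable)
  df
}

#' @param tracks a track tibble (`track_id, frame, x_um, y_um, viable`).
#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  need <- c("track_id", "frame", "x_um", "y_um", "viable")
  if (!all(need %in% names(tracks))) {
    abort(paste0("track table must have columns: ", paste(need, collapse = ",")))
  }
  utils::write.csv(as.data.frame(tracks)[, need], path, row.names = FALSE)
  invisible(path)
}
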