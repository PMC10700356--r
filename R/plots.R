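# ggplot2 visualizations for the main result types.

#' @export
autoplot.binned_profile <- function(object, ...) {
  df <- tibble(bin = seq_along(object$values), value = object$values)
  ggplot(df, aes(x = .data$bin, y = .data$value)) +
    geom_line() +
    geom_point() +
    scale_x_continuous(breaks = seq_along(object$values)) +
    labs(x = if (object$oriented_le_first) "bin (LE → TE)" else "bin",
         y = if (object$normalization == "unit01")
           "normalized intensity" else "intensity") +
    theme_minimal()
}

#' Mean profile with a 95% confidence band across cells
#'
#' Per-bin mean with mean +- 1.96 SEM across cells, the presentation used
#' for population polarity profiles.
#'
#' @param profiles list of [binned_profile()]s (same bin count).
#' @return a ggplot object.
#' @export
plot_profile_band <- function(profiles) {
  mat <- do.call(rbind, lapply(profiles, function(p) p$values))
  df <- tibble(
    bin = seq_len(ncol(mat)),
    mean = colMeans(mat),
    sem = apply(mat, 2, sd) / sqrt(nrow(mat))
  )
  ggplot(df, aes(x = .data$bin, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - 1.96 * .data$sem,
                    ymax = .data$mean + 1.96 * .data$sem), alpha = 0.25) +
    geom_line() +
    scale_x_continuous(breaks = df$bin) +
    labs(x = "bin (LE → TE)", y = "mean intensity (±95% CI)") +
    theme_minimal()
}

#' @export
autoplot.kymograph <- function(object, ...) {
  df <- expand.grid(space = seq_len(nrow(object$data)),
                    frame = seq_len(ncol(object$data)))
  df$intensity <- as.vector(object$data)
  ggplot(df, aes(x = .data$frame, y = .data$space, fill = .data$intensity)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_viridis_c() +
    labs(x = "frame", y = "arc position (px)") +
    theme_minimal()
}

#' @export
autoplot.spacing_result <- function(object, ...) {
  df <- object$per_line |> filter(!.data$skipped)
  ggplot(df, aes(x = .data$distance_nm)) +
    geom_histogram(binwidth = object$step_nm / 2, boundary = 0) +
    geom_vline(xintercept = object$mean_nm, linetype = "dashed") +
    labs(x = "membrane-to-actin-peak distance (nm)", y = "lines") +
    theme_minimal()
}

#' Track overlay plot
#'
#' @param tracks track tibble (`track_id`, `x_um`, `y_um`).
#' @return a ggplot object.
#' @export
plot_tracks <- function(tracks) {
  ggplot(tracks, aes(x = .data$x_um, y = .data$y_um,
                     group = .data$track_id,
                     colour = factor(.data$track_id))) +
    geom_path(show.legend = FALSE) +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}
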