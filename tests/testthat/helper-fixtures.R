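# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# widefield-like multi-cell tracking movie (5 live cells)
tracking_movie <- function() {
  cached("tracking_movie", {
    cfg <- generator_config(image_size_px = c(400, 400), pixel_size_um = 0.325,
                            n_frames = 12, n_cells = 5, speed_um_min = 10,
                            noise_gaussian_sd = 10, dead_fraction = 0,
                            seed = 21)
    generate_cell_movie(cfg)
  })
}

# super-resolution-like single-cell frame for spacing analyses
hires_movie <- function() {
  cached("hires_movie", {
    cfg <- generator_config(image_size_px = c(480, 480),
                            pixel_size_um = 0.0433, n_frames = 2, n_cells = 1,
                            speed_um_min = 2, noise_gaussian_sd = 10, seed = 5)
    generate_cell_movie(cfg)
  })
}

# single-cell movie with a front-depleted membrane-proximal reporter
mpact_movie <- function(depletion = 0.5, seed = 8) {
  key <- sprintf("mpact_%s_%d", depletion, seed)
  cached(key, {
    cfg <- generator_config(image_size_px = c(300, 300),
                            pixel_size_um = 0.1083, n_frames = 2, n_cells = 1,
                            mpact_front_depletion = depletion,
                            noise_gaussian_sd = 10, speed_um_min = 4,
                            seed = seed)
    generate_cell_movie(cfg)
  })
}

# stationary cell with cortical speckle flow
flow_movie <- function(flow_um_min, seed = 11) {
  key <- sprintf("flow_%s_%d", flow_um_min, seed)
  cached(key, {
    cfg <- generator_config(image_size_px = c(160, 160),
                            pixel_size_um = 0.1083, frame_interval_s = 1,
                            n_frames = 60, n_cells = 1, speed_um_min = 0,
                            flow_um_min = flow_um_min,
                            noise_gaussian_sd = 10, seed = seed)
    generate_cell_movie(cfg)
  })
}

# segment the largest in-range cell of a frame and return mask + metrics
largest_cell_mask <- function(movie, frame = 1, channel = "membrane") {
  seg <- segment_cells(movie_frame(movie, frame, channel),
                       movie$pixel_size_um)
  stopifnot(nrow(seg$metrics) >= 1)
  lab <- seg$metrics$label[which.max(seg$metrics$area_um2)]
  list(mask = seg$labels == lab, metrics = seg$metrics)
}

# filled disc / square masks for shape tests
disc_mask <- function(r_px, pad = 4) {
  n <- 2 * (r_px + pad) + 1
  c0 <- r_px + pad + 1
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix((g$x - c0)^2 + (g$y - c0)^2 <= r_px^2, n, n)
}

square_mask <- function(side_px, pad = 4) {
  n <- side_px + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side_px), (pad + 1):(pad + side_px)] <- TRUE
  m
}
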