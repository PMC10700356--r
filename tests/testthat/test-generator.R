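# Synthetic-data generator: determinism, geometry and round-trip fidelity.

test_that("identical config and seed reproduce movies bit for bit", {
  cfg <- generator_config(image_size_px = c(128, 128), pixel_size_um = 0.325,
                          n_frames = 3, n_cells = 2, speed_um_min = 6,
                          seed = 7)
  a <- generate_cell_movie(cfg)
  b <- generate_cell_movie(cfg)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth, b$truth)
})

test_that("per-cell substreams are stable when n_cells changes", {
  base <- list(image_size_px = c(300, 300), pixel_size_um = 0.325,
               n_frames = 2, speed_um_min = 6, seed = 13)
  g2 <- generate_cell_movie(do.call(generator_config, c(base, n_cells = 2)))
  g4 <- generate_cell_movie(do.call(generator_config, c(base, n_cells = 4)))
  shared <- c("speed_um_min", "direction_rad", "area_um2", "circularity")
  expect_equal(as.data.frame(g2$truth[1:2, shared]),
               as.data.frame(g4$truth[1:2, shared]))
})

test_that("a zero-speed noiseless cell does not move", {
  cfg <- generator_config(image_size_px = c(128, 128), pixel_size_um = 0.325,
                          n_frames = 5, n_cells = 1, speed_um_min = 0,
                          noise_gaussian_sd = 0, noise_poisson = FALSE,
                          seed = 3)
  g <- generate_cell_movie(cfg)
  cent <- function(t) {
    m <- movie_frame(g$movie, t, "membrane")
    idx <- which(m > 150, arr.ind = TRUE)
    colMeans(idx)
  }
  expect_equal(cent(1), cent(5), tolerance = 1e-12)
})

test_that("membrane-to-actin peak distance along the front-arc normal matches the configured spacing", {
  # brute-force 1-D scan along the migration axis through the front apex
  cfg <- generator_config(image_size_px = c(480, 480), pixel_size_um = 0.0433,
                          n_frames = 1, n_cells = 1, speed_um_min = 0,
                          le_spacing_nm = 174, noise_gaussian_sd = 0,
                          noise_poisson = FALSE, seed = 2)
  g <- generate_cell_movie(cfg)
  pm <- movie_frame(g$movie, 1, "membrane")
  ac <- movie_frame(g$movie, 1, "actin")
  phi <- g$truth$direction_rad[1]
  c_px <- c(g$truth$x0_um[1], g$truth$y0_um[1]) / 0.0433 + 1
  # scan outward along the axis at sub-pixel steps
  tt <- seq(0, 8 / 0.0433, by = 0.1)
  xs <- c_px[1] + tt * cos(phi); ys <- c_px[2] + tt * sin(phi)
  pmv <- edgewater:::bilinear_sample(pm, xs, ys)
  acv <- edgewater:::bilinear_sample(ac, xs, ys)
  sep_nm <- (tt[which.max(pmv)] - tt[which.max(acv)]) * 0.0433 * 1000
  expect_lt(abs(sep_nm - 174), 0.5 * 43.3)
})

test_that("cell geometry is recovered from noise-free frames", {
  cfg <- generator_config(image_size_px = c(400, 400), pixel_size_um = 0.325,
                          n_frames = 1, n_cells = 4, speed_um_min = 0,
                          noise_gaussian_sd = 0, noise_poisson = FALSE,
                          seed = 31)
  g <- generate_cell_movie(cfg)
  seg <- segment_cells(movie_frame(g$movie, 1, "membrane"), 0.325)
  expect_equal(nrow(seg$metrics), 4)
  # match each detection to the nearest ground-truth cell
  for (i in seq_len(4)) {
    d <- sqrt((seg$metrics$x_um - g$truth$x0_um[i])^2 +
              (seg$metrics$y_um - g$truth$y0_um[i])^2)
    j <- which.min(d)
    expect_lt(abs(seg$metrics$area_um2[j] - g$truth$area_um2[i]) /
                g$truth$area_um2[i], 0.05)
  }
  expect_true(all(g$truth$area_um2 >= 38 & g$truth$area_um2 <= 60))
  # dead cells are round: circularity above any polarized live cell
  expect_true(all(g$truth$circularity < 1))
})

test_that("edge profile stacks honour their stated spacing", {
  # noiseless: every line's brute-force peak separation equals the truth
  g <- generate_edge_profile_stack(20, 174, 0.0433, snr = Inf, seed = 1)
  seps <- vapply(seq_len(20), function(i) {
    oracle_peak_separation_nm(g$stack$pm[i, ], g$stack$actin[i, ], 43.3)
  }, numeric(1))
  expect_true(all(abs(seps - 174) <= 43.3 / 2 + 1e-9))
  # zero spacing: peaks coincide
  g0 <- generate_edge_profile_stack(10, 0, 0.0433, snr = Inf, seed = 1)
  seps0 <- vapply(seq_len(10), function(i) {
    oracle_peak_separation_nm(g0$stack$pm[i, ], g0$stack$actin[i, ], 43.3)
  }, numeric(1))
  expect_true(all(seps0 == 0))
  # noisy: mean brute-force separation within 5 nm of truth
  gn <- generate_edge_profile_stack(100, 174, 0.0433, snr = 10, seed = 3)
  sepn <- vapply(seq_len(100), function(i) {
    oracle_peak_separation_nm(gn$stack$pm[i, ], gn$stack$actin[i, ], 43.3)
  }, numeric(1))
  expect_lt(abs(mean(sepn) - 174), 5)
  # determinism
  gn2 <- generate_edge_profile_stack(100, 174, 0.0433, snr = 10, seed = 3)
  expect_identical(gn$stack$pm, gn2$stack$pm)
})

test_that("volume populations have the requested mode", {
  v <- generate_volume_population(2000, 60, 5, seed = 1)
  expect_true(oracle_hist_mode(v) >= 58 && oracle_hist_mode(v) <= 62)
  expect_identical(v, generate_volume_population(2000, 60, 5, seed = 1))
  expect_equal(generate_volume_population(5, 60, 0), rep(60, 5))
})

test_that("icpms plates invert exactly at zero noise and on average under noise", {
  b <- generate_icpms_batch(c(2, 8, 33), noise_cv = 0)
  out <- icpms_quantify(b$plate, cell_count = 1)
  expect_equal(out$conc_ppb, c(2, 8, 33), tolerance = 1e-9)
  bz <- generate_icpms_batch(c(0, 0), noise_cv = 0)
  outz <- icpms_quantify(bz$plate, cell_count = 1)
  expect_equal(outz$conc_ppb, c(0, 0), tolerance = 1e-9)
  # Monte-Carlo: mean recovered/true ratio within 5% at cv = 0.05
  ratios <- vapply(1:16, function(s) {
    bb <- generate_icpms_batch(10, noise_cv = 0.05, seed = s)
    icpms_quantify(bb$plate)$conc_ppb / 10
  }, numeric(1))
  expect_gt(mean(ratios), 0.95)
  expect_lt(mean(ratios), 1.05)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(pixel_size_um = 0), "pixel_size_um")
  expect_error(generator_config(mpact_front_depletion = 2), "depletion")
  expect_error(generator_config(image_size_px = c(40, 40),
                                pixel_size_um = 0.1083),
               "exceeds image size")
})
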