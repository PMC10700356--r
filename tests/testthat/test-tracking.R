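# Segmentation, thresholding, linking, exclusion rules and speeds.

test_that("triangle threshold follows the geometric construction", {
  # two-delta histogram: threshold strictly between the two values
  v <- c(rep(10, 900), rep(200, 100))
  thr <- triangle_threshold(v)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  # ramp-like histogram: agrees with the exhaustive perpendicular-distance scan
  set.seed(5)
  img <- matrix(c(rep(0, 4000), runif(2000)^2 * 255), 60)
  expect_equal(triangle_threshold(img), oracle_triangle_bin(as.numeric(img)),
               tolerance = 1e-9)
  # constant image has no threshold
  expect_error(triangle_threshold(matrix(3, 5, 5)), "constant")
})

test_that("area filter keeps exactly the inclusive 38-60 um^2 set", {
  px <- 0.5  # 4 px^2 per um^2 -> areas in px = 4 * um^2
  # rectangles with exact pixel counts: 120, 152, 240, 244 px
  dims <- list(c(10, 12), c(8, 19), c(12, 20), c(4, 61))
  n <- 300
  img <- matrix(0, n, n)
  origins <- list(c(40, 40), c(40, 180), c(180, 40), c(180, 150))
  for (k in seq_along(dims)) {
    o <- origins[[k]]; d <- dims[[k]]
    img[o[1]:(o[1] + d[1] - 1), o[2]:(o[2] + d[2] - 1)] <- 1000
  }
  seg <- segment_cells(img + matrix(rnorm(n * n, 10, 1), n), px)
  kept <- sort(seg$metrics$area_um2)
  expect_equal(kept, c(38, 60))
  # blank frame yields no labels
  blank <- matrix(rnorm(400, 10, 1), 20)
  expect_equal(nrow(segment_cells(blank, px)$metrics), 0)
})

test_that("circularity metrics behave like the shape descriptor", {
  d <- shape_metrics(disc_mask(20), 1)
  expect_gte(d$circularity, 0.95)
  # a square at a size where fixed corner-rounding is a small fraction
  s <- shape_metrics(square_mask(60), 1)
  expect_lt(abs(s$circularity - pi / 4), 0.03)
  # scale invariance: same shape, different pixel size
  expect_equal(shape_metrics(disc_mask(20), 0.2)$circularity,
               d$circularity, tolerance = 1e-12)
  # larger digitized disc, same circularity regime
  expect_gte(shape_metrics(disc_mask(40), 1)$circularity, 0.95)
})

test_that("greedy mutual-nearest-neighbour linking keeps cells apart", {
  det <- dplyr::bind_rows(lapply(1:6, function(f) {
    tibble::tibble(frame = f, x_um = c(0 + f, 20 + f), y_um = c(0, 0))
  }))
  tr <- link_tracks(det, max_disp_um = 5)
  expect_equal(dplyr::n_distinct(tr$track_id), 2)
  by_track <- split(tr$x_um, tr$track_id)
  expect_true(all(vapply(by_track, function(x) all(diff(x) == 1), logical(1))))
  # a vanished detection ends its track; reappearance starts a new one
  det2 <- det[!(det$frame %in% 4 & det$x_um > 20), ]
  tr2 <- link_tracks(det2, max_disp_um = 5)
  n2 <- tr2 |> dplyr::count(.data$track_id)
  expect_equal(sort(n2$n), c(2, 3, 6))
})

test_that("exclusion rules: length boundary is strict and dead cells drop", {
  mk <- function(id, nfr, viable = FALSE) {
    tibble::tibble(track_id = id, frame = seq_len(nfr),
                   x_um = seq_len(nfr), y_um = 0, viable = viable)
  }
  tab <- dplyr::bind_rows(mk(1, 19), mk(2, 20), mk(3, 40), mk(4, 40, TRUE))
  out <- filter_tracks(tab, n_frames = 40, min_fraction = 0.5)
  expect_setequal(unique(out$track_id), c(2, 3))
  # idempotent, and never grows
  expect_identical(filter_tracks(out, 40, 0.5), out)
  expect_lte(dplyr::n_distinct(out$track_id), dplyr::n_distinct(tab$track_id))
  # empty in, empty out
  expect_equal(nrow(filter_tracks(tab[0, ], 40, 0.5)), 0)
  # collagen rule at 1/3: the 19-frame track clears 40/3 and is kept
  out3 <- filter_tracks(tab, n_frames = 40, min_fraction = 1 / 3)
  expect_setequal(unique(out3$track_id), c(1, 2, 3))
})

test_that("track speed is path length over duration", {
  tr <- tibble::tibble(frame = 1:2, x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(track_speed(tr, dt_s = 15), 20)  # 5 um / 0.25 min
  still <- tibble::tibble(frame = 1:5, x_um = 0, y_um = 0)
  expect_equal(track_speed(still, 15), 0)
  expect_error(track_speed(tr[1, ], 15), "2 points")
})

test_that("the full chain recovers ground-truth speeds on generated movies", {
  g <- tracking_movie()
  det <- detect_cells(g$movie)
  tr <- filter_tracks(link_tracks(det), n_frames = 12)
  expect_equal(dplyr::n_distinct(tr$track_id), nrow(g$truth))
  sp <- track_speeds(tr, dt_s = 15)
  est <- sort(sp$speed_um_min)
  truth <- sort(g$truth$speed_um_min)
  rel <- abs(est - truth) / truth
  expect_lt(median(rel), 0.05)
})

test_that("dead cells are flagged and excluded from the chain", {
  cfg <- generator_config(image_size_px = c(600, 600), pixel_size_um = 0.325,
                          n_frames = 8, n_cells = 6, speed_um_min = 8,
                          noise_gaussian_sd = 10, dead_fraction = 0.4,
                          seed = 41)
  g <- generate_cell_movie(cfg)
  n_dead <- sum(g$truth$is_dead)
  expect_gt(n_dead, 0)
  det <- detect_cells(g$movie)
  tr <- link_tracks(det)
  kept <- filter_tracks(tr, n_frames = 8)
  expect_equal(dplyr::n_distinct(kept$track_id),
               sum(!g$truth$is_dead))
})
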