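# Polarity profiling: projections, 12-bin profiles, perimeter polarization,
# MPAct/CaaX ratios.

test_that("align_and_project averages aligned ROIs", {
  img <- matrix(runif(101 * 101), 101)
  # identical copies: projection equals the single-cell ROI
  p1 <- align_and_project(list(img), 0, roi_um = c(20, 10), pixel_size_um = 1)
  p2 <- align_and_project(list(img, img, img), c(0, 0, 0), roi_um = c(20, 10),
                          pixel_size_um = 1)
  expect_equal(p1, p2, tolerance = 1e-12)
  # constant images 0 and 2 average to 1
  z <- matrix(0, 41, 41); tw <- matrix(2, 41, 41)
  pm <- align_and_project(list(z, tw), c(0, pi / 3), roi_um = c(10, 5),
                          pixel_size_um = 1)
  expect_true(all(abs(pm - 1) < 1e-9))
  expect_error(align_and_project(list(), numeric(0), 10, 1), "no crops")
})

test_that("projected front-enriched reporters stay front-enriched", {
  cfg <- generator_config(image_size_px = c(260, 260), pixel_size_um = 0.1083,
                          n_frames = 2, n_cells = 1,
                          reporter_front_enrichment = 2,
                          noise_gaussian_sd = 5, speed_um_min = 2, seed = 4)
  g <- generate_cell_movie(cfg)
  lc <- largest_cell_mask(g$movie)
  cx <- round(lc$metrics$x_um[1] / 0.1083) + 1
  cy <- round(lc$metrics$y_um[1] / 0.1083) + 1
  h <- min(65, cx - 1, cy - 1, 260 - cx, 260 - cy)
  crop <- movie_frame(g$movie, 1, "reporter")[(cy - h):(cy + h),
                                              (cx - h):(cx + h)]
  pr <- align_and_project(list(crop), g$truth$direction_rad[1],
                          roi_um = c(14, 7), pixel_size_um = 0.1083)
  nh <- ncol(pr) %/% 2
  expect_gt(mean(pr[, (nh + 1):ncol(pr)]), mean(pr[, 1:nh]))
})

test_that("length profiles bin the axial coordinate LE-first", {
  mask <- matrix(TRUE, 20, 48)
  ramp <- matrix(rep(1:48, each = 20), 20)  # increases toward +x (the LE)
  p <- length_profile(ramp, mask, direction = 0)
  expect_equal(length(p$values), 12)
  expect_true(all(diff(p$values) < 0))  # bin 1 = LE = brightest end
  # all intensity in the front twelfth
  front <- matrix(0, 20, 48); front[, 45:48] <- 7
  pf <- length_profile(front, mask, 0)
  expect_gt(pf$values[1], 0)
  expect_true(all(pf$values[2:12] == 0))
  # constant image: all bins equal
  pc <- length_profile(matrix(5, 20, 48), mask, 0)
  expect_true(all(pc$values == 5))
  # too short along the axis
  expect_error(length_profile(ramp[, 1:8], mask[, 1:8], 0), "shorter")
})

test_that("normalization variants behave and are idempotent", {
  p <- binned_profile(seq(2, 24, by = 2))
  n1 <- normalize01(p)
  expect_equal(min(n1$values), 0)
  expect_equal(max(n1$values), 1)
  expect_equal(normalize01(n1)$values, n1$values)
  pc <- normalize01(binned_profile(rep(3, 12)))
  expect_true(pc$degenerate)
  expect_true(all(pc$values == 0))
  nm <- normalize_max(p)
  expect_equal(max(nm$values), 1)
  expect_equal(normalize_max(nm)$values, nm$values)
})

test_that("LE/TE anchoring flips on the marker peaks with a tie guard", {
  mk <- function(peak) binned_profile(replace(rep(0, 12), peak, 1))
  pr <- list(CDC42 = mk(12), CD44 = mk(1), X = binned_profile(1:12))
  out <- anchor_le_te(pr)
  expect_true(out$flipped)
  expect_equal(out$profiles$X$values, 12:1)
  pr2 <- list(CDC42 = mk(2), CD44 = mk(11))
  out2 <- anchor_le_te(pr2)
  expect_false(out2$flipped)
  expect_false(out2$conflict)
  pr3 <- list(CDC42 = mk(6), CD44 = mk(6))
  out3 <- anchor_le_te(pr3)
  expect_true(out3$conflict)
  expect_equal(out3$profiles$CDC42$values, pr3$CDC42$values)
  # idempotence
  again <- anchor_le_te(out$profiles)
  expect_false(again$flipped)
})

test_that("perimeter polarization matches direct summation", {
  expect_equal(perimeter_polarization(rep(2, 100)), 0.25, tolerance = 1 / 100)
  one <- replace(rep(0, 64), 17, 5)
  expect_equal(perimeter_polarization(one), 1)
  # 90 samples at 1, 10 consecutive at 11 -> (10*11 + 15*1) / 200
  v <- rep(1, 100); v[40:49] <- 11
  expect_equal(perimeter_polarization(v), 0.625)
  # invariance to start-point rotation and intensity scaling
  rot <- c(v[26:100], v[1:25])
  expect_equal(perimeter_polarization(rot), perimeter_polarization(v))
  expect_equal(perimeter_polarization(3 * v), perimeter_polarization(v))
  expect_error(perimeter_polarization(rep(0, 50)), "zero")
})

test_that("mpact polarity is a front/back ratio with guard and symmetry", {
  m <- binned_profile(rep(1, 12)); cx <- binned_profile(rep(2, 12))
  r <- mpact_polarity(m, cx)
  expect_equal(r$polarity, 1)
  expect_true(all(abs(r$ratio$values - 1) < 1e-12))
  # front at half the back ratio
  m2 <- binned_profile(c(rep(0.5, 3), rep(1, 6), rep(1, 3)))
  r2 <- mpact_polarity(m2, binned_profile(rep(1, 12)))
  expect_equal(r2$polarity, 0.5)
  # reversing both profiles inverts the polarity
  rev2 <- mpact_polarity(binned_profile(rev(m2$values)),
                         binned_profile(rep(1, 12)))
  expect_equal(rev2$polarity, 1 / r2$polarity)
  # zero back bins are an error
  mz <- binned_profile(c(rep(1, 9), rep(0, 3)))
  expect_error(mpact_polarity(mz, binned_profile(rep(1, 12))), "back")
})

test_that("mpact polarity recovers the generator's ground truth", {
  for (dep in c(1, 0.5)) {
    g <- mpact_movie(dep)
    lc <- largest_cell_mask(g$movie)
    dirn <- g$truth$direction_rad[1]
    mp <- length_profile(movie_frame(g$movie, 1, "reporter"), lc$mask, dirn)
    cx <- length_profile(movie_frame(g$movie, 1, "membrane"), lc$mask, dirn)
    est <- mpact_polarity(mp, cx)$polarity
    if (dep == 1) {
      expect_lt(abs(est - 1), 0.05)
    } else {
      truth <- g$truth$polarity_ratio[1]
      expect_lt(abs(est - truth) / truth, 0.15)
    }
  }
})

test_that("perimeter polarization of generated cells reflects reporter polarity", {
  g <- mpact_movie(1)  # uniform reporter
  lc <- largest_cell_mask(g$movie)
  pp <- perimeter_profile(movie_frame(g$movie, 1, "reporter"), lc$mask,
                          offset_px = 2)
  est <- perimeter_polarization(pp)
  expect_lt(abs(est - g$truth$perimeter_polarization[1]), 0.05)
})
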