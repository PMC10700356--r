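# Membrane-to-F-actin spacing: straightening, aligned line stacks, peak
# distances, and the spacing-speed correlation.

test_that("a circular membrane ring straightens to a horizontal line", {
  n <- 201; r <- 60
  g <- expand.grid(y = 1:n, x = 1:n)
  d <- sqrt((g$x - 101)^2 + (g$y - 101)^2)
  ring <- matrix(exp(-(d - r)^2 / 8), n, n)
  mask <- matrix(d <= r + 1, n, n)
  band <- trace_and_straighten_edge(ring, ring, mask, direction = 0)
  ridge_rows <- apply(band$pm, 2, which.max)
  expect_true(all(abs(ridge_rows - 15.5) <= 1.5))
  # rotating input and direction together changes nothing material
  band90 <- trace_and_straighten_edge(ring, ring, mask, direction = pi / 2)
  expect_equal(mean(apply(band90$pm, 2, which.max)),
               mean(ridge_rows), tolerance = 0.1)
})

test_that("straightened bands of generated cells hold the PM ridge steady", {
  g <- hires_movie()
  lc <- largest_cell_mask(g$movie)
  band <- trace_and_straighten_edge(movie_frame(g$movie, 1, "membrane"),
                                    movie_frame(g$movie, 1, "actin"),
                                    lc$mask, g$truth$direction_rad[1])
  ridge_rows <- apply(band$pm, 2, which.max)
  expect_true(all(abs(ridge_rows - 15.5) <= 1.5))
})

test_that("perpendicular profile counts and alignment follow the overlap rule", {
  g <- hires_movie()
  lc <- largest_cell_mask(g$movie)
  band <- trace_and_straighten_edge(movie_frame(g$movie, 1, "membrane"),
                                    movie_frame(g$movie, 1, "actin"),
                                    lc$mask, g$truth$direction_rad[1])
  stk <- perpendicular_profiles(band, pixel_size_um = g$movie$pixel_size_um)
  w <- ncol(band$pm)
  expect_equal(nrow(stk$pm), floor((w - 20) / 10) + 1)
  # every aligned line has its membrane peak at (refined) position 0
  peaks <- vapply(seq_len(nrow(stk$pm)), function(i) {
    which.max(stk$pm[i, ]) - stk$pm_peak[i]
  }, numeric(1))
  expect_true(all(abs(peaks) <= 0.5))
  expect_error(perpendicular_profiles(list(pm = band$pm[, 1:10, drop = FALSE],
                                           actin = band$actin[, 1:10, drop = FALSE]),
                                      pixel_size_um = 0.0433),
               "narrower")
})

test_that("actin peak distances honour the interior window rule", {
  step <- 43.3
  idx <- 1:40
  pm <- exp(-((idx - 15) * step)^2 / (2 * 70^2))
  # noiseless peak at 174 nm
  ac <- exp(-((idx - 15) * step - 174)^2 / (2 * 90^2))
  stk <- edgewater:::new_profile_stack(rbind(pm), rbind(ac), step_nm = step)
  r <- actin_peak_distance(stk)
  expect_lt(abs(r$mean_nm - 174), step / 2)
  # coincident peaks give zero
  stk0 <- edgewater:::new_profile_stack(rbind(pm), rbind(pm), step_nm = step)
  expect_lt(abs(actin_peak_distance(stk0)$mean_nm), 1)
  # a larger maximum outside the window loses to a secondary peak inside
  ac2 <- 1.0 * exp(-((idx - 15) * step - 450)^2 / (2 * 30^2)) +
         0.5 * exp(-((idx - 15) * step - 100)^2 / (2 * 30^2))
  stk2 <- edgewater:::new_profile_stack(rbind(pm), rbind(ac2), step_nm = step)
  r2 <- actin_peak_distance(stk2, window_nm = 400)
  expect_lt(abs(r2$mean_nm - 100), 25)
})

test_that("spacing estimates are unbiased at SNR 10 for both region defaults", {
  for (truth in c(174, 43)) {
    g <- generate_edge_profile_stack(100, truth, 0.0433, snr = 10, seed = 1)
    r <- actin_peak_distance(g$stack)
    expect_lt(abs(r$mean_nm - truth), 43.3 / 2)
  }
})

test_that("spacing is invariant to intensity scaling and offsets", {
  g <- generate_edge_profile_stack(30, 174, 0.0433, snr = 20, seed = 9)
  base <- actin_peak_distance(g$stack)$mean_nm
  st2 <- edgewater:::new_profile_stack(3 * g$stack$pm + 7,
                                       0.5 * g$stack$actin + 2,
                                       step_nm = g$stack$step_nm)
  expect_equal(actin_peak_distance(st2)$mean_nm, base, tolerance = 1e-9)
})

test_that("shrinking the window below the true spacing changes the answer", {
  g <- generate_edge_profile_stack(50, 174, 0.0433, snr = Inf, seed = 2)
  wide <- actin_peak_distance(g$stack, window_nm = 400)$mean_nm
  narrow <- actin_peak_distance(g$stack, window_nm = 100)$mean_nm
  expect_lt(narrow, wide - 20)
})

test_that("the straightening pipeline recovers both configured spacings", {
  g <- hires_movie()
  lc <- largest_cell_mask(g$movie)
  dirn <- g$truth$direction_rad[1]
  le <- cell_edge_spacing(g$movie, lc$mask, dirn, region = "leading edge")
  side <- cell_edge_spacing(g$movie, lc$mask, dirn, region = "side")
  expect_lt(abs(le$mean_nm - g$truth$le_spacing_nm[1]), 22)
  expect_lt(abs(side$mean_nm - g$truth$side_spacing_nm[1]), 22)
})

test_that("spacing-speed correlation reproduces the Pearson formula", {
  d <- tibble::tibble(speed = c(1, 2, 3, 4), spacing = c(2, 1, 3, 4))
  r <- spacing_speed_correlation(d, spacing, speed)
  # direct covariance formula
  rr <- sum(scale(d$speed)[, 1] * scale(d$spacing)[, 1]) / 3
  expect_equal(r$r, rr, tolerance = 1e-12)
  up <- tibble::tibble(x = 1:5, y = 2 * (1:5) + 1)
  expect_equal(spacing_speed_correlation(up, y, x)$r, 1)
  dn <- tibble::tibble(x = 1:5, y = -3 * (1:5))
  expect_equal(spacing_speed_correlation(dn, y, x)$r, -1)
  cst <- tibble::tibble(x = 1:5, y = rep(1, 5))
  expect_error(spacing_speed_correlation(cst, y, x), "constant")
})
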