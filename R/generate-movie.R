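# Synthetic movie renderer.
#
# Cell geometry: two half-ellipses sharing the minor axis (blunt front,
# longer tapered rear). In the cell frame the boundary radius at polar angle
# theta (theta = 0 pointing along the migration direction) is
#   R(theta) = 1 / sqrt(cos^2/a^2 + sin^2/b^2),  a = a_front or a_rear.
# All rendered intensity is truncated at the geometric outline r = R with a
# half-pixel cosine taper, and the membrane ridge sits 1.5 sigma inside the
# outline, so the support of the rendered signal *is* the cell footprint:
# a threshold anywhere between background and the interior fill recovers
# the analytic area.

cell_shape_radius <- function(theta, a_front, a_rear, b) {
  a <- ifelse(cos(theta) >= 0, a_front, a_rear)
  1 / sqrt(cos(theta)^2 / a^2 + sin(theta)^2 / b^2)
}

# Front-arc weight: 1 within +-60 deg of the migration direction, cosine
# rolloff to 0 at 75 deg (sharp enough that side-region measurements in the
# 75-135 deg window see the pure side value).
front_weight <- function(theta) {
  at <- abs(((theta + pi) %% (2 * pi)) - pi)  # fold to [0, pi]
  w <- numeric(length(at))
  w[at <= pi / 3] <- 1
  mid <- at > pi / 3 & at < 5 * pi / 12
  w[mid] <- cos((at[mid] - pi / 3) / (pi / 12) * (pi / 2))^2
  w
}

# Angle between the outward radial direction and the outline normal, on the
# theta grid of shape_arclength(): tan(psi) = (dR/dtheta) / R. Offsets meant
# as *normal* distances are applied radially as offset / cos(psi).
shape_normal_angle <- function(a_front, a_rear, b, n = 721) {
  th <- seq(0, pi, length.out = n)
  r <- cell_shape_radius(th, a_front, a_rear, b)
  dr <- numeric(n)
  dr[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / (th[3] - th[1])
  list(theta = th, psi = atan2(abs(dr), r))
}

# Numeric perimeter of the two-half-ellipse outline (optionally offset
# radially inward) and the arc-length map s(theta) for theta in [0, pi]
# (shape is mirror-symmetric).
shape_arclength <- function(a_front, a_rear, b, n = 721, offset = 0) {
  th <- seq(0, pi, length.out = n)
  r <- pmax(0.05, cell_shape_radius(th, a_front, a_rear, b) - offset)
  dr <- c(diff(r) / diff(th)[1], 0)
  ds <- sqrt(r^2 + dr^2)
  s <- c(0, cumsum((ds[-n] + ds[-1]) / 2 * diff(th)))
  list(theta = th, s = s, half_perimeter = s[n])
}

# Inward offset of the membrane ridge from the geometric outline.
ridge_offset_um <- function(cfg) 0.5 * cfg$pixel_size_um + 1.5 * cfg$psf_sigma_um

# Frozen 1-D periodic speckle pattern for one cell: sum of harmonics with
# random amplitudes/phases, normalized to unit SD. `x` in um, period in um.
make_speckle_fun <- function(period_um, n_harmonics = 18) {
  k <- seq_len(n_harmonics)
  amp <- rnorm(n_harmonics) / sqrt(k)
  phs <- runif(n_harmonics, 0, 2 * pi)
  f <- function(x) {
    out <- numeric(length(x))
    for (i in k) out <- out + amp[i] * cos(2 * pi * i * x / period_um + phs[i])
    out
  }
  sdv <- sd(f(seq(0, period_um, length.out = 512)))
  function(x) f(x) / sdv
}

# Draw one cell's realized parameters from its private substream.
draw_cell_params <- function(cfg, mults, cell_seed) {
  with_seed(cell_seed, {
    area <- runif(1, cfg$cell_area_um2_range[1], cfg$cell_area_um2_range[2])
    aspect <- runif(1, 1.6, 2.2)
    is_dead <- runif(1) < cfg$dead_fraction
    direction <- runif(1, 0, 2 * pi)
    speed <- cfg$speed_um_min * mults$speed * runif(1, 0.85, 1.15)
    if (is_dead) {
      r0 <- sqrt(area / pi)
      a_front <- a_rear <- b <- r0
      speed <- 0
    } else {
      b <- sqrt(area / (pi * aspect))
      len <- 2 * aspect * b
      a_front <- 0.42 * len
      a_rear <- 0.58 * len
    }
    perim <- 2 * shape_arclength(a_front, a_rear, b)$half_perimeter
    # speckles live on the cortical band just inside the outline; advect
    # them along that band's own arc length so sampled flow speed is exact
    arc <- shape_arclength(a_front, a_rear, b, offset = ridge_offset_um(cfg))
    normal_angle <- shape_normal_angle(a_front, a_rear, b)
    speckle <- make_speckle_fun(arc$half_perimeter)
    pos_u <- runif(2)          # placement, mapped to the field later
    dir_jitter <- runif(1)     # reserved draw (keeps stream layout stable)
    list(
      area = area, aspect = aspect, is_dead = is_dead, direction = direction,
      speed = speed, a_front = a_front, a_rear = a_rear, b = b,
      arc = arc, normal_angle = normal_angle,
      perimeter = perim, circularity = 4 * pi * area / perim^2,
      le_spacing_nm = if (is_dead) cfg$side_spacing_nm * mults$spacing
                      else cfg$le_spacing_nm * mults$spacing,
      side_spacing_nm = cfg$side_spacing_nm * mults$spacing,
      flow_um_min = if (is_dead) 0 else cfg$flow_um_min * mults$flow,
      speckle = speckle, pos_u = pos_u
    )
  })
}

# Place a cell: start position such that the whole path stays in the field.
place_cell <- function(p, cfg) {
  w_um <- (cfg$image_size_px[2] - 1) * cfg$pixel_size_um
  h_um <- (cfg$image_size_px[1] - 1) * cfg$pixel_size_um
  half <- max(p$a_front, p$a_rear, p$b) + 0.6
  path <- p$speed * (cfg$n_frames - 1) * cfg$frame_interval_s / 60
  dx <- path * cos(p$direction); dy <- path * sin(p$direction)
  usable_x <- w_um - 2 * half - abs(dx)
  usable_y <- h_um - 2 * half - abs(dy)
  if (usable_x < 0 || usable_y < 0) {
    abort("movie field too small for the configured speed and duration")
  }
  x0 <- half + max(0, -dx) + p$pos_u[1] * usable_x
  y0 <- half + max(0, -dy) + p$pos_u[2] * usable_y
  c(x0, y0)
}

# Render one cell's clean contribution into the 4 channel matrices.
# `channels` is a list of matrices modified in place (returned).
render_cell <- function(channels, p, center_um, t_s, cfg) {
  px <- cfg$pixel_size_um
  ny <- nrow(channels[[1]]); nx <- ncol(channels[[1]])
  sig_m <- cfg$psf_sigma_um
  sig_a <- sqrt(cfg$psf_sigma_um^2 + (cfg$cortex_sigma_nm / 1000)^2)
  hc <- 0.5 * px                      # outline taper half-width
  delta_m <- ridge_offset_um(cfg)     # ridge offset inside the outline
  half <- max(p$a_front, p$a_rear, p$b) + 3 * sig_a + 2 * px
  c0 <- floor((center_um[1] - half) / px) + 1
  c1 <- ceiling((center_um[1] + half) / px) + 1
  r0 <- floor((center_um[2] - half) / px) + 1
  r1 <- ceiling((center_um[2] + half) / px) + 1
  cols <- max(1, c0):min(nx, c1)
  rows <- max(1, r0):min(ny, r1)
  if (!length(cols) || !length(rows)) return(channels)
  gx <- (cols - 1) * px - center_um[1]
  gy <- (rows - 1) * px - center_um[2]
  dx <- matrix(gx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  dy <- matrix(gy, nrow = length(rows), ncol = length(cols))
  ca <- cos(p$direction); sa <- sin(p$direction)
  u <- dx * ca + dy * sa
  w <- -dx * sa + dy * ca
  th <- atan2(w, u)
  r <- sqrt(u^2 + w^2)
  R <- cell_shape_radius(th, p$a_front, p$a_rear, p$b)
  # compact-support outline taper
  clip <- pmin(1, pmax(0, (R - r) / hc))
  clip <- 0.5 - 0.5 * cos(pi * clip)
  inside <- clip > 0
  if (!any(inside)) return(channels)
  fw <- front_weight(th)
  s_um <- (p$side_spacing_nm + (p$le_spacing_nm - p$side_spacing_nm) * fw) / 1000
  # offsets are normal distances from the outline; convert to radial
  th_fold <- abs(((th + pi) %% (2 * pi)) - pi)
  psi <- approx(p$normal_angle$theta, p$normal_angle$psi, xout = th_fold,
                rule = 2, ties = "ordered")$y
  cpsi <- pmax(0.3, cos(psi))
  Rm <- R - delta_m / cpsi
  Ra <- Rm - s_um / cpsi
  fill <- 1200 * clip
  ridge_m <- 3000 * exp(-(r - Rm)^2 / (2 * sig_m^2)) * clip
  # cortical actin band with frozen speckles advected rearward along the arc
  arcpos <- approx(p$arc$theta, p$arc$s,
                   xout = abs(((th + pi) %% (2 * pi)) - pi),
                   rule = 2, ties = "ordered")$y
  spk <- 1 + 0.45 * pmax(-1.8, pmin(1.8, p$speckle(arcpos - p$flow_um_min * t_s / 60)))
  amp_a <- 2600 * (0.75 + 0.5 * fw)
  ridge_a <- amp_a * exp(-(r - Ra)^2 / (2 * sig_a^2)) * clip * spk
  # axial reporter modulation: linear from g_front at the tip to 1 at the rear
  g_front <- p$g_front
  g <- 1 + (g_front - 1) * pmax(0, pmin(1, (u + p$a_rear) / (p$a_front + p$a_rear)))
  rep_ch <- g * (fill + ridge_m)
  via <- if (p$is_dead) 2000 * clip else 0
  add <- function(m, v) { m[rows, cols] <- m[rows, cols] + v; m }
  channels$membrane <- add(channels$membrane, fill + ridge_m)
  channels$actin <- add(channels$actin, 300 * clip + ridge_a)
  channels$reporter <- add(channels$reporter, rep_ch)
  if (p$is_dead) channels$viability <- add(channels$viability, via)
  channels
}

# Analytic (noise-free) mask of one cell at a given centre.
analytic_mask <- function(p, center_um, cfg) {
  px <- cfg$pixel_size_um
  ny <- cfg$image_size_px[1]; nx <- cfg$image_size_px[2]
  gx <- ((seq_len(nx)) - 1) * px - center_um[1]
  gy <- ((seq_len(ny)) - 1) * px - center_um[2]
  dx <- matrix(gx, nrow = ny, ncol = nx, byrow = TRUE)
  dy <- matrix(gy, nrow = ny, ncol = nx)
  ca <- cos(p$direction); sa <- sin(p$direction)
  u <- dx * ca + dy * sa
  w <- -dx * sa + dy * ca
  r <- sqrt(u^2 + w^2)
  R <- cell_shape_radius(atan2(w, u), p$a_front, p$a_rear, p$b)
  r <= R
}

#' Generate a synthetic multi-channel movie of migrating T cells
#'
#' Renders polarized cells (blunt-front / tapered-rear two-half-ellipse
#' outline) translating at their realized speed, with four channels:
#' `membrane` (outline ridge plus interior fill), `actin` (cortical band
#' displaced inward from the membrane ridge by the leading-edge spacing on
#' the front arc and the side spacing laterally, carrying speckles that flow
#' rearward at the configured rate), `reporter` (membrane-shaped signal with
#' configurable front enrichment/depletion), and `viability` (bright only in
#' dead cells, which are round and stationary). Identical `(config,
#' condition)` including the seed give bit-identical output.
#'
#' @param config a [generator_config()].
#' @param condition condition label resolved against
#'   `config$condition_multipliers` (falls back to `"default"`).
#' @return A list with elements `movie` (a [cell_movie()]) and `truth`
#'   (a tibble of per-cell ground truth: realized speed, direction, area,
#'   circularity, spacings, polarity ratio, perimeter polarization, flow,
#'   start position, viability).
#' @export
generate_cell_movie <- function(config, condition = "default") {
  cfg <- config
  validate_generator_config(cfg)
  mults <- condition_mults(cfg, condition)
  ny <- cfg$image_size_px[1]; nx <- cfg$image_size_px[2]
  g_front <- cfg$reporter_front_enrichment * cfg$mpact_front_depletion
  cells <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    p <- draw_cell_params(cfg, mults, substream_seed(cfg$seed, i))
    p$g_front <- if (p$is_dead) 1 else g_front
    p$start_um <- place_cell(p, cfg)
    cells[[i]] <- p
  }
  blank <- function() matrix(0, ny, nx)
  arr <- array(0, dim = c(cfg$n_frames, 4, ny, nx))
  clean_first <- NULL
  for (t in seq_len(cfg$n_frames)) {
    t_s <- (t - 1) * cfg$frame_interval_s
    ch <- list(membrane = blank(), actin = blank(), reporter = blank(),
               viability = blank())
    for (p in cells) {
      ctr <- p$start_um +
        p$speed * t_s / 60 * c(cos(p$direction), sin(p$direction))
      ch <- render_cell(ch, p, ctr, t_s, cfg)
    }
    if (t == 1) clean_first <- ch
    stack <- list(ch$membrane + 100, ch$actin + 100, ch$reporter + 100,
                  ch$viability + 100)
    for (k in 1:4) arr[t, k, , ] <- stack[[k]]
  }
  # per-cell ground truth for the polarity readouts, computed on the clean
  # first frame with the analytic mask (the realized value of the rendered
  # geometry, before noise)
  truth <- purrr::imap(cells, function(p, i) {
    mask <- analytic_mask(p, p$start_um, cfg)
    pol <- NA_real_; perim_pol <- NA_real_
    if (sum(mask) > 50 && !p$is_dead) {
      mp <- length_profile(clean_first$reporter, mask, p$direction)
      cx <- length_profile(clean_first$membrane, mask, p$direction)
      pol <- tryCatch(mpact_polarity(mp, cx)$polarity,
                      error = function(e) NA_real_)
      perim_pol <- tryCatch({
        pp <- perimeter_profile(clean_first$reporter, mask,
                                offset_px = (0.5 * cfg$pixel_size_um +
                                             1.5 * cfg$psf_sigma_um) /
                                  cfg$pixel_size_um)
        perimeter_polarization(pp)
      }, error = function(e) NA_real_)
    }
    tibble(
      cell_id = i, speed_um_min = p$speed, direction_rad = p$direction,
      area_um2 = p$area, circularity = p$circularity,
      le_spacing_nm = p$le_spacing_nm, side_spacing_nm = p$side_spacing_nm,
      polarity_ratio = pol, perimeter_polarization = perim_pol,
      flow_um_min = p$flow_um_min, x0_um = p$start_um[1],
      y0_um = p$start_um[2], is_dead = p$is_dead
    )
  }) |> bind_rows()
  # noise, applied from a movie-level substream after all cells are rendered
  arr <- with_seed(substream_seed(cfg$seed, 0), {
    out <- arr
    if (cfg$noise_poisson) out[] <- rpois(length(out), lambda = out)
    if (cfg$noise_gaussian_sd > 0) {
      out[] <- out + rnorm(length(out), sd = cfg$noise_gaussian_sd)
    }
    out[] <- pmin(65535, pmax(0, round(out)))
    out
  })
  movie <- cell_movie(arr, pixel_size_um = cfg$pixel_size_um,
                      dt_s = cfg$frame_interval_s,
                      channel_names = c("membrane", "actin", "reporter",
                                        "viability"))
  list(movie = movie, truth = truth)
}

#' Synthetic z-stack of one cell for volumetry
#'
#' Renders a spherical cell of the requested volume as a membrane-bounded
#' mask per z-slice, the readout used by slice-summation volumetry.
#'
#' @param volume_um3 true cell volume (um^3 = fL).
#' @param pixel_size_um pixel size (um/px).
#' @param z_spacing_um slice spacing (um).
#' @param n_z number of slices (cell centred in the stack).
#' @param image_size_px matrix size per slice.
#' @return list with `masks` (list of logical matrices), `dz_um`, and
#'   `volume_um3` (the truth).
#' @export
generate_cell_zstack <- function(volume_um3, pixel_size_um = 0.1083,
                                 z_spacing_um = 1, n_z = 7,
                                 image_size_px = c(96, 96)) {
  r <- (3 * volume_um3 / (4 * pi))^(1 / 3)
  zc <- (seq_len(n_z) - (n_z + 1) / 2) * z_spacing_um
  ny <- image_size_px[1]; nx <- image_size_px[2]
  cx <- (nx - 1) / 2 * pixel_size_um; cy <- (ny - 1) / 2 * pixel_size_um
  gx <- (seq_len(nx) - 1) * pixel_size_um - cx
  gy <- (seq_len(ny) - 1) * pixel_size_um - cy
  dx2 <- matrix(gx^2, ny, nx, byrow = TRUE)
  dy2 <- matrix(gy^2, ny, nx)
  masks <- lapply(zc, function(z) {
    r2 <- r^2 - z^2
    if (r2 <= 0) matrix(FALSE, ny, nx) else dx2 + dy2 <= r2
  })
  list(masks = masks, dz_um = z_spacing_um, volume_um3 = volume_um3)
}
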