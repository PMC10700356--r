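# Direct fixtures with known ground truth: leading-edge profile stacks,
# Coulter-style volume populations, and ICP-MS plates.

#' Generate a synthetic stack of leading-edge line profiles
#'
#' Emulates the per-line readout of the edge-straightening analysis without
#' the straightening step: each line holds two Gaussian peaks, one per
#' channel (plasma membrane and F-actin), separated by `true_spacing_nm`
#' plus a small per-line jitter; both the jitter and the additive noise
#' scale as `1/snr`. The cell interior lies toward increasing sample index.
#'
#' @param n_lines number of perpendicular lines.
#' @param true_spacing_nm membrane-to-actin-peak distance (nm, >= 0).
#' @param pixel_size_um sampling step along the line (um).
#' @param snr amplitude-to-noise ratio; `Inf` for noiseless lines.
#' @param seed RNG seed.
#' @param sigma_pm_nm,sigma_actin_nm Gaussian widths of the two peaks (nm).
#' @return list with `stack` (a `profile_stack`) and `truth` (a list holding
#'   `true_spacing_nm` and the per-line realized spacings).
#' @export
generate_edge_profile_stack <- function(n_lines, true_spacing_nm,
                                        pixel_size_um = 0.0433, snr = Inf,
                                        seed = 1, sigma_pm_nm = 70,
                                        sigma_actin_nm = 90) {
  if (n_lines < 1) abort("`n_lines` must be >= 1")
  if (true_spacing_nm < 0) abort("`true_spacing_nm` must be >= 0")
  step_nm <- pixel_size_um * 1000
  n_ext <- ceiling(600 / step_nm)
  n_int <- ceiling(1100 / step_nm)
  n_pos <- n_ext + n_int + 1
  i0 <- n_ext + 1
  with_seed(seed, {
    jit_c <- rnorm(n_lines, 0, 0.3)                    # px, alignment jitter
    jit_s <- if (is.finite(snr)) rnorm(n_lines, 0, 20 / snr) else rep(0, n_lines)
    idx <- seq_len(n_pos)
    pm <- matrix(0, n_lines, n_pos)
    actin <- matrix(0, n_lines, n_pos)
    for (i in seq_len(n_lines)) {
      c_pm <- i0 + jit_c[i]
      c_ac <- c_pm + (true_spacing_nm + jit_s[i]) / step_nm
      pm[i, ] <- exp(-((idx - c_pm) * step_nm)^2 / (2 * sigma_pm_nm^2))
      actin[i, ] <- 0.9 * exp(-((idx - c_ac) * step_nm)^2 / (2 * sigma_actin_nm^2))
    }
    if (is.finite(snr)) {
      pm <- pm + matrix(rnorm(length(pm), 0, 1 / snr), n_lines)
      actin <- actin + matrix(rnorm(length(actin), 0, 0.9 / snr), n_lines)
    }
    stack <- new_profile_stack(pm, actin, step_nm = step_nm,
                               source = "synthetic")
    list(stack = stack,
         truth = list(true_spacing_nm = true_spacing_nm,
                      per_line_nm = true_spacing_nm + jit_s))
  })
}

#' Generate a Coulter-style cell-volume population
#'
#' Log-normal sample parameterized by its mode (the instrument's modal
#' volume readout) and standard deviation; the histogram mode at 1 fL
#' binning recovers `mode_fl` for populations of ~2000 cells at moderate
#' dispersion.
#'
#' @param n number of cells (>= 1).
#' @param mode_fl modal volume (fL).
#' @param sd_fl population standard deviation (fL); 0 gives a degenerate
#'   point mass at the mode.
#' @param seed RNG seed.
#' @return numeric vector of volumes (fL).
#' @export
generate_volume_population <- function(n, mode_fl, sd_fl, seed = 1) {
  if (n < 1) abort("`n` must be >= 1")
  if (mode_fl <= 0 || sd_fl < 0) abort("`mode_fl` must be > 0, `sd_fl` >= 0")
  if (sd_fl == 0) return(rep(mode_fl, n))
  # solve for the log-sd giving the requested mode and sd:
  # mode = exp(mu - s^2), var = m^2 (e^{s^2} - 1) e^{3 s^2}
  target <- (sd_fl / mode_fl)^2
  f <- function(s) (exp(s^2) - 1) * exp(3 * s^2) - target
  s <- uniroot(f, c(1e-8, 2), tol = 1e-12)$root
  mu <- log(mode_fl) + s^2
  with_seed(seed, rlnorm(n, meanlog = mu, sdlog = s))
}

#' Generate a synthetic ICP-MS plate with internal standard and calibration
#'
#' Emulates a raw-intensity plate: repeat blanks, a six-point external
#' calibration series, and sample rows, each carrying analyte counts and
#' internal-standard (e.g. Ga) counts. A shared multiplicative drift factor
#' per row couples analyte and internal standard, so internal-standard
#' normalization removes it; measurement noise is multiplicative with CV
#' `noise_cv`. At `noise_cv = 0` the quantification chain inverts the plate
#' exactly.
#'
#' @param true_conc true sample concentrations (ppb).
#' @param calib_levels six distinct calibration concentrations (ppb).
#' @param is_counts nominal internal-standard counts.
#' @param blank_counts analyte background counts.
#' @param sensitivity detector sensitivity (counts per ppb).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_blanks number of repeat blank rows.
#' @param seed RNG seed.
#' @return list with `plate` (tibble: `sample_id`, `type`, `conc_ppb`,
#'   `analyte_counts`, `is_counts`) and `truth` (= `true_conc`).
#' @export
generate_icpms_batch <- function(true_conc, calib_levels = c(0, 1, 5, 10, 50, 100),
                                 is_counts = 1e5, blank_counts = 200,
                                 sensitivity = 40, noise_cv = 0,
                                 n_blanks = 3, seed = 1) {
  if (length(calib_levels) != 6 || anyDuplicated(calib_levels)) {
    abort("`calib_levels` must be 6 distinct concentrations")
  }
  if (sensitivity <= 0) abort("`sensitivity` must be > 0")
  rows <- tibble(
    sample_id = c(paste0("blank", seq_len(n_blanks)),
                  paste0("std", seq_along(calib_levels)),
                  paste0("sample", seq_along(true_conc))),
    type = c(rep("blank", n_blanks), rep("standard", length(calib_levels)),
             rep("sample", length(true_conc))),
    conc_ppb = c(rep(NA_real_, n_blanks), calib_levels,
                 rep(NA_real_, length(true_conc))),
    true_ppb = c(rep(0, n_blanks), calib_levels, true_conc)
  )
  with_seed(seed, {
    m <- nrow(rows)
    drift <- 1 + noise_cv * rnorm(m)
    mnoise <- 1 + noise_cv * rnorm(m)
    rows$analyte_counts <- (blank_counts + sensitivity * rows$true_ppb) *
      drift * mnoise
    rows$is_counts <- is_counts * drift
    rows$true_ppb <- NULL
    list(plate = rows, truth = true_conc)
  })
}
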