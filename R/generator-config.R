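#' Configuration for the synthetic cell-movie generator
#'
#' Defaults follow the acquisition geometry of the assays the package
#' quantifies: 0.1083 um/px super-resolution-like pixels (0.325 um/px for a
#' widefield-like 20x field), one frame every 15 s, cell areas of 38-60 um^2,
#' a membrane-to-cortical-actin spacing of 174 nm at the leading edge and
#' 43 nm on the sides, and 7 z-slices at 1 um spacing for volumetry.
#'
#' @param image_size_px integer pair (ny, nx).
#' @param pixel_size_um physical pixel size (um/px).
#' @param frame_interval_s frame interval (s).
#' @param n_frames number of frames.
#' @param n_cells number of cells to place.
#' @param cell_area_um2_range min/max cell area (um^2).
#' @param speed_um_min nominal migration speed (um/min).
#' @param le_spacing_nm membrane-to-peak-F-actin spacing at the leading edge
#'   (nm).
#' @param side_spacing_nm same, at the cell sides (nm).
#' @param cortex_sigma_nm Gaussian width of the cortical actin band (nm).
#' @param reporter_front_enrichment multiplicative front enrichment of the
#'   reporter channel (>= 0; 1 = uniform).
#' @param mpact_front_depletion multiplicative front depletion of the
#'   membrane-proximal-actin reporter, in `[0, 1]` (1 = no depletion).
#' @param flow_um_min cortical retrograde speckle flow (um/min).
#' @param psf_sigma_um Gaussian PSF sigma (um).
#' @param noise_gaussian_sd additive read-noise SD (counts).
#' @param noise_poisson apply Poisson shot noise?
#' @param dead_fraction probability a cell is rendered dead (round,
#'   stationary, viability-positive).
#' @param z_spacing_um z spacing for volumetric stacks (um).
#' @param n_z number of z slices.
#' @param condition_multipliers named list of condition -> list of
#'   multipliers on `speed`, `spacing`, `flow` (e.g.
#'   `list(WNKi = list(speed = 0.4, spacing = 0.5, flow = 0.3))`).
#' @param seed root seed; per-cell substreams are derived from it by
#'   counter-based splitting so adding cells never reshuffles existing ones.
#' @return a `generator_config` list.
#' @export
generator_config <- function(image_size_px = c(256, 256),
                             pixel_size_um = 0.1083,
                             frame_interval_s = 15,
                             n_frames = 20,
                             n_cells = 5,
                             cell_area_um2_range = c(38, 60),
                             speed_um_min = 12,
                             le_spacing_nm = 174,
                             side_spacing_nm = 43,
                             cortex_sigma_nm = 120,
                             reporter_front_enrichment = 1,
                             mpact_front_depletion = 1,
                             flow_um_min = 5,
                             psf_sigma_um = 0.1,
                             noise_gaussian_sd = 15,
                             noise_poisson = TRUE,
                             dead_fraction = 0,
                             z_spacing_um = 1,
                             n_z = 7,
                             condition_multipliers = list(
                               default = list(),
                               vehicle = list(),
                               WNKi = list(speed = 0.4, spacing = 0.5, flow = 0.3)
                             ),
                             seed = 1) {
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames), n_cells = as.integer(n_cells),
    cell_area_um2_range = cell_area_um2_range, speed_um_min = speed_um_min,
    le_spacing_nm = le_spacing_nm, side_spacing_nm = side_spacing_nm,
    cortex_sigma_nm = cortex_sigma_nm,
    reporter_front_enrichment = reporter_front_enrichment,
    mpact_front_depletion = mpact_front_depletion,
    flow_um_min = flow_um_min, psf_sigma_um = psf_sigma_um,
    noise_gaussian_sd = noise_gaussian_sd, noise_poisson = noise_poisson,
    dead_fraction = dead_fraction, z_spacing_um = z_spacing_um,
    n_z = as.integer(n_z), condition_multipliers = condition_multipliers,
    seed = seed
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  pos <- c("pixel_size_um", "frame_interval_s", "psf_sigma_um",
           "cortex_sigma_nm", "z_spacing_um")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(paste0("`", f, "` must be > 0"))
    }
  }
  if (cfg$speed_um_min < 0 || cfg$flow_um_min < 0) {
    abort("speeds must be >= 0")
  }
  if (cfg$le_spacing_nm < 0 || cfg$side_spacing_nm < 0) {
    abort("spacings must be >= 0")
  }
  if (cfg$reporter_front_enrichment < 0) {
    abort("`reporter_front_enrichment` must be >= 0")
  }
  if (cfg$mpact_front_depletion < 0 || cfg$mpact_front_depletion > 1) {
    abort("`mpact_front_depletion` must be in [0, 1]")
  }
  if (cfg$dead_fraction < 0 || cfg$dead_fraction > 1) {
    abort("`dead_fraction` must be in [0, 1]")
  }
  if (length(cfg$image_size_px) != 2 || any(cfg$image_size_px < 8)) {
    abort("`image_size_px` must be a pair of ints >= 8")
  }
  r <- cfg$cell_area_um2_range
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1]) {
    abort("`cell_area_um2_range` must be an increasing positive pair")
  }
  # largest possible cell length (aspect ratio drawn up to 2.2)
  lmax_um <- 2 * sqrt(2.2 * r[2] / pi)
  if (lmax_um / cfg$pixel_size_um > min(cfg$image_size_px)) {
    abort("cell diameter exceeds image size: enlarge `image_size_px`")
  }
  invisible(cfg)
}

# Resolve the (speed, spacing, flow) multipliers for a condition label.
condition_mults <- function(cfg, condition) {
  cm <- cfg$condition_multipliers
  if (!condition %in% names(cm)) {
    if ("default" %in% names(cm)) condition <- "default"
    else abort(paste0("unknown condition: ", condition))
  }
  m <- cm[[condition]]
  list(speed = m$speed %||% 1, spacing = m$spacing %||% 1,
       flow = m$flow %||% 1)
}
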