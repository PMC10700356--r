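# Volumetry, medium tonicity design, and ICP-MS / NMR normalization chains.

#' Cell volume from a z-stack of masks
#'
#' Sums the slice mask areas times the z spacing (the slice-summation
#' volumetry used on 3-D reconstructions of membrane-labelled cells).
#'
#' @param zstack_masks list of logical matrices (>= 1 slice).
#' @param dz_um z spacing (um).
#' @param pixel_size_um pixel size (um/px).
#' @return volume in um^3 (= fL).
#' @export
stack_volume <- function(zstack_masks, dz_um, pixel_size_um) {
  if (length(zstack_masks) < 1) abort("need at least one slice")
  areas <- vapply(zstack_masks, function(m) sum(m) * pixel_size_um^2,
                  numeric(1))
  sum(areas) * dz_um
}

#' Modal volume of a cell population
#'
#' Centre of the maximal 1-fL histogram bin (ties to the lower bin), the
#' Coulter-counter modal-volume readout; requires >= 100 cells for a stable
#' mode.
#'
#' @param volumes numeric vector of volumes (fL).
#' @param bin_fl histogram bin width (fL).
#' @return modal volume (fL).
#' @export
modal_volume <- function(volumes, bin_fl = 1) {
  if (length(volumes) < 100) abort("mode unstable: need >= 100 volumes")
  centre <- round(volumes / bin_fl)
  tab <- table(centre)
  as.numeric(names(tab)[which.max(tab)]) * bin_fl
}

#' Median volume of a cell population
#'
#' Companion aggregator to [modal_volume()] for instrument summaries
#' reported as medians.
#'
#' @inheritParams modal_volume
#' @export
median_volume <- function(volumes) median(volumes)

#' Osmolarity after partial replacement with osmolyte-free solution
#'
#' Replacing a fraction `f` of an isotonic medium with an osmotically
#' inactive (NaCl-free) solution scales osmolarity linearly:
#' `iso_osm * (1 - f)`, reported to one decimal. With the 292 mOsm/l
#' isotonic baseline this generates the tonicity series
#' 277.4, 262.8, 248.2, 233.6 mOsm/l for f = 5, 10, 15, 20%.
#'
#' @param iso_osm isotonic osmolarity (mOsm/l).
#' @param f replaced fraction in `[0, 1]`.
#' @return osmolarity (mOsm/l), one decimal.
#' @export
replace_fraction_osmolarity <- function(iso_osm, f) {
  if (any(f < 0) || any(f > 1)) abort("`f` must be in [0, 1]")
  round(iso_osm * (1 - f), 1)
}

#' Percent tonicity reduction relative to isotonic medium
#'
#' @param iso_osm isotonic osmolarity (mOsm/l).
#' @param hypo_osm reduced osmolarity (0 < hypo <= iso).
#' @return percentage reduction `100 * (iso - hypo) / iso`.
#' @export
percent_tonicity_reduction <- function(iso_osm, hypo_osm) {
  if (any(hypo_osm <= 0) || any(hypo_osm > iso_osm)) {
    abort("`hypo_osm` must be in (0, iso_osm]")
  }
  100 * (iso_osm - hypo_osm) / iso_osm
}

#' Non-ionic osmolyte supplement restoring isotonicity
#'
#' Millimolar amount of an inert non-ionic osmolyte (d-sorbitol, L-glucose)
#' needed to raise `base_osm` to `target_osm`; 1 mM contributes 1 mOsm/l.
#'
#' @param base_osm starting osmolarity (mOsm/l).
#' @param target_osm target osmolarity (mOsm/l, >= base).
#' @return supplement amount (mM).
#' @export
isotonic_supplement <- function(base_osm, target_osm) {
  if (any(target_osm < base_osm)) abort("`target_osm` must be >= `base_osm`")
  target_osm - base_osm
}

#' Fit a six-point external calibration curve
#'
#' Ordinary least squares of blank-corrected, internal-standard-normalized
#' intensity on concentration over the six calibration standards.
#'
#' @param plate ICP-MS plate tibble (see [generate_icpms_batch()]) with
#'   blank, standard, and sample rows.
#' @return a `calibration_curve`: list with `slope` (normalized counts per
#'   ppb), `intercept`, `points` (tibble), `blank_norm` (mean
#'   internal-standard-normalized blank signal).
#' @export
icpms_calibration <- function(plate) {
  if (any(plate$is_counts <= 0)) abort("internal-standard counts must be > 0")
  blanks <- plate |> filter(.data$type == "blank")
  stds <- plate |> filter(.data$type == "standard")
  if (nrow(blanks) < 1) abort("need at least one blank")
  if (nrow(stds) != 6 || anyDuplicated(stds$conc_ppb)) {
    abort("need a six-point calibration series with distinct concentrations")
  }
  blank_norm <- mean(blanks$analyte_counts / blanks$is_counts)
  pts <- stds |>
    mutate(corrected = .data$analyte_counts / .data$is_counts - blank_norm) |>
    select("conc_ppb", "corrected")
  fit <- lm(corrected ~ conc_ppb, data = pts)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) abort("degenerate calibration curve")
  structure(list(slope = slope, intercept = intercept, points = pts,
                 blank_norm = blank_norm),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> slope %.4g /ppb, intercept %.4g, blank %.4g\n",
              x$slope, x$intercept, x$blank_norm))
  invisible(x)
}

#' Concentrations from raw ICP-MS intensities
#'
#' The instrument normalization chain: raw analyte counts are divided by
#' the internal-standard (Ga/Ce) counts, blank-corrected by the mean
#' normalized blank signal, converted with the external calibration curve,
#' and normalized to cell number. Negative blank-corrected signals are
#' clamped to zero with a flag.
#'
#' @param raw_counts analyte counts (vector).
#' @param is_counts matching internal-standard counts (> 0).
#' @param curve a `calibration_curve` from [icpms_calibration()].
#' @param cell_count number of cells in each sample (> 0).
#' @return tibble: `conc_ppb`, `per_cell`, `clamped`.
#' @export
icpms_concentration <- function(raw_counts, is_counts, curve, cell_count) {
  if (any(is_counts <= 0)) abort("internal-standard counts must be > 0")
  if (any(cell_count <= 0)) abort("`cell_count` must be > 0")
  corrected <- raw_counts / is_counts - curve$blank_norm
  clamped <- corrected < 0
  corrected[clamped] <- 0
  conc <- (corrected - curve$intercept) / curve$slope
  conc[clamped] <- 0
  tibble(conc_ppb = conc, per_cell = conc / cell_count, clamped = clamped)
}

#' Quantify a whole ICP-MS plate
#'
#' Fits the calibration on the plate's blanks and standards, then converts
#' every sample row.
#'
#' @param plate plate tibble (see [generate_icpms_batch()]).
#' @param cell_count cells per sample.
#' @return tibble of sample rows with `conc_ppb`, `per_cell`, `clamped`.
#' @export
icpms_quantify <- function(plate, cell_count = 1) {
  curve <- icpms_calibration(plate)
  samples <- plate |> filter(.data$type == "sample")
  res <- icpms_concentration(samples$analyte_counts, samples$is_counts,
                             curve, cell_count)
  dplyr::bind_cols(samples |> select("sample_id"), res)
}

#' Fold change relative to a control group
#'
#' Each value divided by the control mean (the cross-site normalization
#' used to combine element measurements, and the 2H2O fold-change readout).
#'
#' @param values numeric vector.
#' @param control_values control group (mean must be > 0).
#' @return fold changes.
#' @export
fold_vs_control <- function(values, control_values) {
  cm <- mean(control_values)
  if (!is.finite(cm) || cm <= 0) abort("control mean must be > 0")
  values / cm
}

#' Internal-standard-normalized heavy-water NMR signal
#'
#' Peak integral of the 2H2O resonance divided by that of the 2H-labelled
#' 1,4-dioxane internal standard.
#'
#' @param water_integral 2H2O peak integral (>= 0).
#' @param dioxane_integral dioxane peak integral (> 0).
#' @return normalized signal.
#' @export
nmr_water_signal <- function(water_integral, dioxane_integral) {
  if (any(dioxane_integral <= 0)) abort("internal standard must be > 0")
  water_integral / dioxane_integral
}
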