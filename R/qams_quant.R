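# External-standard calibration, relative correction factors, and
# single-marker (QAMS) content computation.
#
# QAMS quantifies several analytes from one calibrated internal standard:
# the relative correction factor f_x = (W_is * A_x) / (W_x * A_is),
# measured on mixed reference solutions, converts the analyte's peak area
# to internal-standard-equivalent response, so that
# content_x = (A_x * content_is) / (f_x * A_is).

#' Fit an external-standard calibration line
#'
#' Ordinary least squares of area on amount injected; `r` is the Pearson
#' correlation of the points; the linear range is the span of the fitted
#' amounts. Two points give the exact interpolating line.
#'
#' @param amount_ug amounts injected (micrograms).
#' @param area corresponding peak areas.
#' @param analyte,wavelength_nm identification carried on the curve.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r`, `linear_range_ug`, `analyte`, `wavelength_nm`.
#' @export
fit_calibration <- function(amount_ug, area, analyte = "",
                            wavelength_nm = NA_real_) {
  if (length(amount_ug) != length(area))
    stop_domain("amount and area must have equal length")
  if (length(amount_ug) < 2L)
    stop_domain("calibration needs at least 2 points")
  if (stats::var(amount_ug) == 0)
    stop_domain("degenerate calibration: zero amount variance")
  fit <- stats::lm(area ~ amount_ug)
  r <- if (length(amount_ug) == 2L) 1 else stats::cor(amount_ug, area)
  calibration_curve(slope = unname(stats::coef(fit)[2L]),
                    intercept = unname(stats::coef(fit)[1L]),
                    r = r, linear_range_ug = range(amount_ug),
                    analyte = analyte, wavelength_nm = wavelength_nm)
}

#' Construct a calibration curve
#'
#' @param slope area per microgram (> 0 for a usable curve).
#' @param intercept area at zero amount.
#' @param r correlation coefficient (|r| <= 1).
#' @param linear_range_ug `c(low, high)` amounts, low < high.
#' @param analyte,wavelength_nm identification.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, r = NA_real_,
                              linear_range_ug = c(0, Inf), analyte = "",
                              wavelength_nm = NA_real_) {
  if (!is.na(r) && abs(r) > 1 + 1e-12) stop_domain("|r| must be <= 1")
  if (linear_range_ug[1] >= linear_range_ug[2])
    stop_domain("linear range low must be below high")
  structure(list(slope = slope, intercept = intercept, r = r,
                 linear_range_ug = as.numeric(linear_range_ug),
                 analyte = analyte, wavelength_nm = wavelength_nm),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s at %g nm: area = %.4g * amount %+.4g (r = %.4f)\n",
              x$analyte, x$wavelength_nm, x$slope, x$intercept, x$r))
  invisible(x)
}

#' Sample preparation constants
#'
#' Mass of powder weighed, extraction flask volume, and injection volume;
#' these convert an on-column amount (micrograms) to a content
#' (mg per g of powder). Defaults: 0.5 g in 25 mL, 5 uL injected.
#'
#' @param sample_mass_g mass weighed (g).
#' @param extract_volume_mL volumetric flask volume (mL).
#' @param injection_volume_uL injection volume (uL).
#' @return An object of class `sample_prep`.
#' @export
sample_prep <- function(sample_mass_g = 0.5, extract_volume_mL = 25,
                        injection_volume_uL = 5) {
  assert_scalar_pos(sample_mass_g, "sample_mass_g")
  assert_scalar_pos(extract_volume_mL, "extract_volume_mL")
  assert_scalar_pos(injection_volume_uL, "injection_volume_uL")
  structure(list(sample_mass_g = sample_mass_g,
                 extract_volume_mL = extract_volume_mL,
                 injection_volume_uL = injection_volume_uL),
            class = "sample_prep")
}

#' External-standard content from a peak area
#'
#' Inverts the calibration line (`amount = (area - intercept) / slope`,
#' micrograms on column) and converts to content in mg per g of powder:
#' `amount * (extract volume / injection volume) / sample mass / 1000`.
#' Amounts outside the curve's linear range produce a warning, not an
#' error, so a QC report never aborts on a single out-of-range batch.
#'
#' @param area peak area (vectorised).
#' @param curve a [calibration_curve()].
#' @param prep a [sample_prep()].
#' @return Content in mg per g.
#' @examples
#' esm_content(26.373, calibration_curve(26.30, 0.073))  # 10 mg/g
#' @export
esm_content <- function(area, curve, prep = sample_prep()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop_domain("calibration slope must be positive")
  amount_ug <- (area - curve$intercept) / curve$slope
  out <- amount_ug < curve$linear_range_ug[1] - 1e-12 |
    amount_ug > curve$linear_range_ug[2] + 1e-12
  if (any(out))
    warning(sprintf("%d inverted amount(s) outside the linear range [%g, %g] ug (%s)",
                    sum(out), curve$linear_range_ug[1],
                    curve$linear_range_ug[2], curve$analyte))
  amount_ug * (prep$extract_volume_mL * 1000 / prep$injection_volume_uL) /
    prep$sample_mass_g / 1000
}

#' Relative correction factor
#'
#' `f_x = (W_is * A_x) / (W_x * A_is)`: the analyte's detector response
#' per unit concentration relative to the internal standard's, measured
#' on a mixed reference solution. Invariant under common rescaling of all
#' areas and of all concentrations.
#'
#' @param W_is,A_is internal-standard concentration (ug/mL) and peak area.
#' @param W_x,A_x analyte concentration (ug/mL) and peak area.
#' @return The dimensionless correction factor (vectorised).
#' @export
rcf <- function(W_is, A_is, W_x, A_x) {
  if (any(c(W_is, A_is, W_x, A_x) <= 0))
    stop_domain("concentrations and areas must all be positive")
  (W_is * A_x) / (W_x * A_is)
}

#' Aggregate replicate correction factors
#'
#' @param replicates numeric vector of replicate `f` values (>= 2).
#' @param analyte,wavelength_nm identification.
#' @return An object of class `rcf_set`: `replicates`, `mean_f` (full
#'   precision), `mean_reported` (rounded half-up to 3 decimals, the
#'   tabulation convention), `rsd_pct`.
#' @export
aggregate_rcf <- function(replicates, analyte = "", wavelength_nm = NA_real_) {
  if (length(replicates) < 2L)
    stop_domain("need at least 2 replicate correction factors")
  if (any(replicates <= 0)) stop_domain("correction factors must be positive")
  structure(list(analyte = analyte, wavelength_nm = wavelength_nm,
                 replicates = replicates, mean_f = mean(replicates),
                 mean_reported = round_half_up(mean(replicates), 3),
                 rsd_pct = rsd(replicates)),
            class = "rcf_set")
}

#' @export
print.rcf_set <- function(x, ...) {
  cat(sprintf("<rcf_set> %s at %g nm: mean f = %.3f (RSD %.2f%%, n = %d)\n",
              x$analyte, x$wavelength_nm, x$mean_reported, x$rsd_pct,
              length(x$replicates)))
  invisible(x)
}

#' Check correction-factor reproducibility across conditions
#'
#' Correction factors measured on different instruments/columns are
#' reproducible when the RSD of the per-condition means stays below the
#' threshold (3 % by convention).
#'
#' @param sets data frame with columns `analyte`, `wavelength_nm`,
#'   `mean_f` (one row per measurement condition), or a list of
#'   [aggregate_rcf()] sets.
#' @param max_rsd_pct acceptance threshold on the pooled RSD.
#' @return Data frame with `analyte`, `wavelength_nm`, `n_conditions`,
#'   `rsd_pct`, `pass`; analyte groups with fewer than 2 conditions are
#'   skipped with a warning.
#' @export
check_rcf_reproducibility <- function(sets, max_rsd_pct = 3.0) {
  if (is.list(sets) && !is.data.frame(sets) &&
      all(vapply(sets, inherits, logical(1), "rcf_set"))) {
    sets <- data.frame(
      analyte = vapply(sets, `[[`, character(1), "analyte"),
      wavelength_nm = vapply(sets, `[[`, numeric(1), "wavelength_nm"),
      mean_f = vapply(sets, `[[`, numeric(1), "mean_f"))
  }
  groups <- split(sets, interaction(sets$analyte, sets$wavelength_nm,
                                    drop = TRUE))
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 2L) {
      warning("analyte group skipped (fewer than 2 conditions): ",
              g$analyte[1L])
      return(NULL)
    }
    r <- rsd(g$mean_f)
    data.frame(analyte = g$analyte[1L], wavelength_nm = g$wavelength_nm[1L],
               n_conditions = nrow(g), rsd_pct = r, pass = r <= max_rsd_pct)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Single-marker (QAMS) content
#'
#' `content_x = (A_x * content_is) / (f_x * A_is)`: the analyte's content
#' from its own peak area, the internal standard's peak area and content
#' in the same run, and the pre-established correction factor. With zero
#' calibration intercepts and a correction factor derived from the same
#' calibration data this is algebraically identical to the
#' external-standard content.
#'
#' @param A_x analyte peak area (vectorised).
#' @param f_x relative correction factor (> 0).
#' @param A_is internal-standard peak area in the same chromatogram.
#' @param is_content internal-standard content (mg per g) from ESM.
#' @return Content in mg per g.
#' @export
qams_content <- function(A_x, f_x, A_is, is_content) {
  if (any(f_x <= 0)) stop_domain("correction factor must be positive")
  if (any(A_is <= 0)) stop_domain("internal-standard area must be positive")
  (A_x * is_content) / (f_x * A_is)
}

#' Spike recovery rate
#'
#' `100 * (detected - original) / spiked`, the accuracy metric of
#' spike-recovery experiments.
#'
#' @param detected,original,spiked amounts in consistent units
#'   (vectorised); `spiked > 0`.
#' @return Recovery in percent.
#' @export
recovery_rate <- function(detected, original, spiked) {
  if (any(spiked <= 0)) stop_domain("spiked amount must be positive")
  100 * (detected - original) / spiked
}

#' Relative error of QAMS vs ESM content
#'
#' `100 * (qams - esm) / esm`; the method-agreement metric, reported to
#' 2 decimals in content tables (use `digits` for the reporting
#' convention, `NULL` for full precision).
#'
#' @param qams,esm contents in the same unit (vectorised); `esm > 0`.
#' @param digits decimals for half-up rounding, or `NULL`.
#' @return Relative error in percent.
#' @export
relative_error <- function(qams, esm, digits = NULL) {
  if (any(esm <= 0)) stop_domain("reference (ESM) content must be positive")
  re <- 100 * (qams - esm) / esm
  if (!is.null(digits)) re <- round_half_up(re, digits)
  re
}

#' Summarise relative errors of a content report
#'
#' @param reports data frame with at least `re_pct` and optionally
#'   `analyte`.
#' @return List with `min_re_pct`, `max_re_pct` and `by_analyte` (range
#'   per analyte when labels are present).
#' @export
re_summary <- function(reports) {
  if (!nrow(reports)) stop_domain("need at least one report row")
  re <- reports$re_pct
  by_analyte <- NULL
  if (!is.null(reports$analyte)) {
    by_analyte <- do.call(rbind, lapply(split(reports, reports$analyte),
      function(g) data.frame(analyte = g$analyte[1L],
                             min_re_pct = min(g$re_pct),
                             max_re_pct = max(g$re_pct),
                             n = nrow(g))))
    rownames(by_analyte) <- NULL
  }
  list(min_re_pct = min(re), max_re_pct = max(re), by_analyte = by_analyte)
}
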