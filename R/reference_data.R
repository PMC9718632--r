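# Packaged reference datasets from the published dual-wavelength
# HPLC-QAMS quality study of Yinqiao powder: calibration lines for the
# seven marker analytes, the six-replicate relative-correction-factor
# series with their reported means/RSDs, per-batch contents by the
# external-standard and single-marker methods, and the mixed-standard
# concentrations. All values transcribed from the printed study tables;
# used as fixtures and as ground truth for the synthetic generator.

read_extdata <- function(name) {
  path <- system.file("extdata", name, package = "qamsfp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published calibration lines of the seven marker analytes
#'
#' One ordinary-least-squares line (`area = slope * amount + intercept`)
#' per analyte per wavelength, with correlation coefficient and linear
#' range of the amount injected (micrograms on column). Forsythoside A,
#' the internal standard, is calibrated at both 237 and 327 nm.
#'
#' @return Data frame with columns `wavelength_nm`, `analyte`, `slope`,
#'   `intercept`, `r`, `range_low_ug`, `range_high_ug`.
#' @export
ref_calibration_lines <- function() read_extdata("calibration_lines.csv")

#' Published relative-correction-factor replicates
#'
#' Six replicate relative correction factors per analyte against the
#' forsythoside A internal standard (phillyrin and arctiin at 237 nm; the
#' four caffeoylquinic acids at 327 nm).
#'
#' @return Data frame with columns `wavelength_nm`, `analyte`,
#'   `replicate`, `f`.
#' @export
ref_rcf_replicates <- function() read_extdata("rcf_replicates.csv")

#' Reported relative-correction-factor means and RSDs
#'
#' The study's reported mean and RSD per analyte, computed from unrounded
#' instrument areas (so the reported RSDs can differ slightly from RSDs
#' recomputed from the 3-decimal replicates).
#'
#' @return Data frame with columns `wavelength_nm`, `analyte`, `mean_f`,
#'   `rsd_pct`.
#' @export
ref_rcf_means <- function() read_extdata("rcf_means.csv")

#' Published per-batch contents by ESM and QAMS
#'
#' Contents (mg per g of powder) of the marker analytes in ten batches by
#' the external-standard method (ESM) and the single-marker method
#' (QAMS), with the printed relative errors. The internal standard
#' forsythoside A appears with its ESM content only.
#'
#' @return Data frame with columns `wavelength_nm`, `batch`, `analyte`,
#'   `esm_mg_g`, `qams_mg_g`, `re_printed_pct`.
#' @export
ref_batch_contents <- function() read_extdata("batch_contents.csv")

#' Mixed-standard solution concentrations
#'
#' Concentrations (micrograms per mL) of the seven reference substances in
#' the mixed standard solutions used for calibration and correction-factor
#' measurement.
#'
#' @return Data frame with columns `analyte`, `conc_ug_ml`.
#' @export
ref_standard_mix <- function() read_extdata("standard_mix.csv")
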