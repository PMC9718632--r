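# End-to-end pipeline: simulate/ingest -> detect -> shear/screen -> match
# -> fingerprint + similarity -> PCA / PLS-DA -> QAMS content report.

fnv1a32 <- function(txt) {
  # tiny config fingerprint for the run log (FNV-1a, 32 bit)
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    # xor against a byte touches only the low 8 bits; keep h as double
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # exact 32-bit modular multiply via 16-bit limbs
    h <- (((h %/% 65536) * 16777619) %% 65536 * 65536 +
            (h %% 65536) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' @param design a [panel_design()]; defaults to the packaged
#'   ten-batch design seeded with `seed`.
#' @param seed RNG seed for the whole run.
#' @param match a [match_config()].
#' @param prep a [sample_prep()].
#' @param similarity_metric `"cosine"` or `"correlation"`.
#' @param pca_mode `"correlation"` or `"covariance"`.
#' @param plsda_classes class labels for PLS-DA, one per batch; `NULL`
#'   defaults to a first-half/second-half demonstration split.
#' @param use_detection run peak detection on the synthetic traces
#'   (`TRUE`, the full instrument-like path) or use the generator's
#'   ground-truth peak tables (`FALSE`, faster).
#' @param fingerprint_wavelength_nm channel used for fingerprinting.
#' @param locate_tol_rrv,locate_tol_delta_min localization tolerances for
#'   marker peaks (relative retention fraction; minutes).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, seed = 1L,
                            match = match_config(), prep = sample_prep(),
                            similarity_metric = "cosine",
                            pca_mode = "correlation", plsda_classes = NULL,
                            use_detection = TRUE,
                            fingerprint_wavelength_nm = 237,
                            locate_tol_rrv = 0.02,
                            locate_tol_delta_min = 1.0) {
  design <- design %||% default_panel_design(seed = seed)
  structure(list(design = design, seed = as.integer(seed), match = match,
                 prep = prep, similarity_metric = similarity_metric,
                 pca_mode = pca_mode, plsda_classes = plsda_classes,
                 use_detection = isTRUE(use_detection),
                 fingerprint_wavelength_nm = fingerprint_wavelength_nm,
                 locate_tol_rrv = locate_tol_rrv,
                 locate_tol_delta_min = locate_tol_delta_min),
            class = "pipeline_config")
}

# localization plan for the seven markers: the four caffeoylquinic acids
# early in the run drift little in absolute time (located by rt
# difference for the first two, by relative retention for the rest)
marker_plan <- data.frame(
  analyte = c("neochlorogenic acid", "chlorogenic acid",
              "isochlorogenic acid A", "isochlorogenic acid C",
              "phillyrin", "arctiin"),
  wavelength_nm = c(327, 327, 327, 327, 237, 237),
  method = c("delta", "delta", "rrv", "rrv", "rrv", "rrv"),
  stringsAsFactors = FALSE)

locate_marker <- function(table, is_rt, method, expected_rrv, expected_delta,
                          cfg) {
  if (method == "rrv") {
    locate_by_relative_retention(table, is_rt, expected_rrv,
                                 tol = cfg$locate_tol_rrv)
  } else {
    locate_by_rt_difference(table, is_rt, expected_delta,
                            tol = cfg$locate_tol_delta_min)
  }
}

#' Run the full quality-evaluation pipeline
#'
#' Simulates (or ingests) a batch panel, detects peaks, shears the
#' solvent front, matches common peaks across batches, screens them by
#' area, builds the median-method reference fingerprint and per-batch
#' similarities, runs PCA (and PLS-DA with VIP screening when class
#' labels are available), and computes the dual-wavelength QAMS content
#' report against external-standard calibration. When `outdir` is given,
#' all tables are written as CSV plus a JSON run log (package version,
#' seed, config fingerprint, per-stage peak counts); outputs are
#' byte-reproducible given the seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created if missing).
#' @return A list bundle: `matrix`, `fingerprint`, `similarities`,
#'   `validation`, `pca`, `vip`, `key_components`, `curves`, `rcfs`,
#'   `contents`, `re_summary`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  log <- list(package = "qamsfp",
              version = as.character(utils::packageVersion("qamsfp")),
              seed = config$seed,
              config_hash = fnv1a32(jsonlite::toJSON(
                list(seed = config$seed,
                     n_batches = design$n_batches,
                     metric = config$similarity_metric,
                     pca_mode = config$pca_mode,
                     use_detection = config$use_detection),
                auto_unbox = TRUE)),
              stages = list())

  sim <- make_batch_panel(design, seed = config$seed,
                          traces = config$use_detection)
  wl_fp <- as.character(config$fingerprint_wavelength_nm)

  get_tables <- function(wl) {
    if (config$use_detection) {
      lapply(sim$traces[[wl]], function(tr)
        detect_peaks(tr, sample_id = paste0("det_", tr$wavelength_nm)))
    } else {
      sim$truth[[wl]]$tables
    }
  }
  raw_tables <- get_tables(wl_fp)
  for (i in seq_along(raw_tables)) {
    attr(raw_tables[[i]], "sample_id") <- sim$truth[[wl_fp]]$batch_ids[i]
  }
  log$stages$detected <- vapply(raw_tables, nrow, integer(1))

  sheared <- lapply(raw_tables, shear_solvent_region,
                    cut_min = config$match$solvent_cut_min)
  log$stages$after_shear <- vapply(sheared, nrow, integer(1))

  panel <- batch_panel(sheared)
  cfg_nofilter <- config$match
  cfg_nofilter$min_area <- 0
  matched_raw <- match_common_peaks(panel, cfg_nofilter)
  mat <- filter_min_area(matched_raw, config$match$min_area)
  log$stages$matched_clusters <- length(matched_raw$peak_ids)
  log$stages$common_peaks <- length(mat$peak_ids)

  fp <- median_reference(mat)
  sims <- panel_similarities(mat, fp, metric = config$similarity_metric)
  valid <- validation_report(mat, ref_peak_id = 1L)

  pca_res <- pca(mat, mode = config$pca_mode)
  classes <- config$plsda_classes %||%
    rep(c("first_half", "second_half"),
        c(ceiling(design$n_batches / 2), floor(design$n_batches / 2)))
  pls <- nipals_plsda(mat$areas, classes)
  vip_scores <- vip(pls)
  keys <- screen_key_components(vip_scores)

  qams <- pipeline_qams(sim, config, log)
  log <- qams$log

  bundle <- list(matrix = mat, fingerprint = fp, similarities = sims,
                 validation = valid, pca = pca_res, vip = vip_scores,
                 key_components = keys, curves = qams$curves,
                 rcfs = qams$rcfs, contents = qams$contents,
                 re_summary = qams$re_summary, log = log)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

pipeline_qams <- function(sim, config, log) {
  design <- sim$design
  lines <- ref_calibration_lines()
  mix <- ref_standard_mix()
  inj_uL <- config$prep$injection_volume_uL

  # calibration: noiseless six-point series on each published line,
  # refitted (slope/intercept recovered exactly)
  curves <- lapply(seq_len(nrow(lines)), function(i) {
    li <- lines[i, ]
    amounts <- seq(li$range_low_ug, li$range_high_ug, length.out = 6)
    ser <- make_calibration_series(li$slope, li$intercept, amounts,
                                   linear_range_ug = c(li$range_low_ug,
                                                       li$range_high_ug))
    fit_calibration(ser$amount_ug, ser$area, analyte = li$analyte,
                    wavelength_nm = li$wavelength_nm)
  })
  names(curves) <- paste(lines$analyte, lines$wavelength_nm)
  curve_of <- function(analyte, wl) curves[[paste(analyte, wl)]]

  # correction factors from the mixed standard solution: areas follow the
  # calibration lines at the standard concentrations
  std_area <- function(analyte, wl) {
    cv <- curve_of(analyte, wl)
    conc <- mix$conc_ug_ml[mix$analyte == analyte]
    cv$slope * conc * inj_uL / 1000 + cv$intercept
  }
  W_is <- mix$conc_ug_ml[mix$analyte == "forsythoside A"]
  rcfs <- marker_plan
  rcfs$f <- vapply(seq_len(nrow(marker_plan)), function(i) {
    wl <- marker_plan$wavelength_nm[i]
    an <- marker_plan$analyte[i]
    rcf(W_is, std_area("forsythoside A", wl),
        mix$conc_ug_ml[mix$analyte == an], std_area(an, wl))
  }, numeric(1))

  # expected localization parameters from the design's marker positions
  truth_rts <- vapply(design$common_peaks, `[[`, numeric(1), "rt_mean_min")
  truth_labels <- vapply(design$common_peaks, `[[`, character(1), "analyte")
  rt_is <- truth_rts[truth_labels == "forsythoside A"]

  wls <- unique(marker_plan$wavelength_nm)
  contents <- list()
  for (wl in wls) {
    wl_chr <- as.character(wl)
    tables <- if (config$use_detection) {
      lapply(sim$traces[[wl_chr]], detect_peaks)
    } else {
      sim$truth[[wl_chr]]$tables
    }
    tables <- lapply(tables, shear_solvent_region,
                     cut_min = config$match$solvent_cut_min)
    is_curve <- curve_of("forsythoside A", wl)
    for (b in seq_along(tables)) {
      tb <- tables[[b]]
      is_peak <- locate_by_rt_difference(tb, is_rt = rt_is,
                                         expected_delta = 0,
                                         tol = config$locate_tol_delta_min)
      is_content <- esm_content(is_peak$area, is_curve, config$prep)
      contents[[length(contents) + 1L]] <- data.frame(
        wavelength_nm = wl, batch = b, analyte = "forsythoside A",
        esm_mg_g = is_content, qams_mg_g = NA_real_, re_pct = NA_real_)
      plan_wl <- marker_plan[marker_plan$wavelength_nm == wl, ]
      for (i in seq_len(nrow(plan_wl))) {
        an <- plan_wl$analyte[i]
        rt_an <- truth_rts[truth_labels == an]
        pk <- tryCatch(
          locate_marker(tb, is_peak$rt_min, plan_wl$method[i],
                        expected_rrv = rt_an / rt_is,
                        expected_delta = rt_an - rt_is, cfg = config),
          qamsfp_notfound_error = function(e) NULL)
        if (is.null(pk)) next
        esm <- esm_content(pk$area, curve_of(an, wl), config$prep)
        qams <- qams_content(pk$area, rcfs$f[rcfs$analyte == an],
                             is_peak$area, is_content)
        contents[[length(contents) + 1L]] <- data.frame(
          wavelength_nm = wl, batch = b, analyte = an, esm_mg_g = esm,
          qams_mg_g = qams, re_pct = relative_error(qams, esm))
      }
    }
  }
  contents <- do.call(rbind, contents)
  log$stages$quantified <- sum(!is.na(contents$qams_mg_g))
  list(curves = curves, rcfs = rcfs, contents = contents,
       re_summary = re_summary(contents[!is.na(contents$re_pct), ]),
       log = log)
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(outdir, name)
  write_common_peak_matrix(bundle$matrix, out("common_peaks"))
  utils::write.csv(data.frame(peak_id = bundle$fingerprint$peak_ids,
                              reference_rt_min = bundle$fingerprint$reference_rts,
                              reference_area = bundle$fingerprint$reference_areas),
                   out("fingerprint_reference.csv"), row.names = FALSE)
  utils::write.csv(data.frame(batch_id = names(bundle$similarities),
                              similarity = unname(bundle$similarities)),
                   out("similarities.csv"), row.names = FALSE)
  utils::write.csv(bundle$validation, out("validation_report.csv"),
                   row.names = FALSE)
  utils::write.csv(scree_table(bundle$pca), out("eigenvalues.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(peak = colnames(bundle$matrix$areas),
                              bundle$pca$loadings, check.names = FALSE),
                   out("loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(peak = names(bundle$vip),
                              vip = unname(bundle$vip)),
                   out("vip.csv"), row.names = FALSE)
  utils::write.csv(bundle$contents, out("content_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$re_summary[c("min_re_pct", "max_re_pct")],
                       out("re_summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$log, out("run_log.json"), auto_unbox = TRUE)
  invisible(outdir)
}

#' Recompute the method-agreement report from the packaged study contents
#'
#' Loads the packaged per-batch ESM/QAMS contents, recomputes every
#' relative error from the content pairs (half-up, 2 decimals), and
#' summarises the range. The printed relative errors travel alongside
#' for comparison.
#'
#' @return List with `report` (data frame incl. recomputed `re_pct`) and
#'   `summary` (from [re_summary()]).
#' @export
recompute_reference_report <- function() {
  contents <- ref_batch_contents()
  quant <- contents[!is.na(contents$qams_mg_g), ]
  quant$re_pct <- relative_error(quant$qams_mg_g, quant$esm_mg_g, digits = 2)
  list(report = quant, summary = re_summary(quant))
}

#' Write a synthetic panel to disk
#'
#' Materialises a panel design as trace CSVs, ground-truth peak-table
#' CSVs, and a JSON manifest of the design (including the seed), so a
#' run can be reproduced from the manifest alone.
#'
#' @param design a [panel_design()].
#' @param outdir output directory.
#' @param seed overrides the design seed.
#' @return `outdir`, invisibly.
#' @export
simulate_panel_files <- function(design = default_panel_design(),
                                 outdir, seed = NULL) {
  sim <- make_batch_panel(design, seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (wl in names(sim$truth)) {
    for (b in seq_along(sim$truth[[wl]]$tables)) {
      id <- sim$truth[[wl]]$batch_ids[b]
      write_trace(sim$traces[[wl]][[b]],
                  file.path(outdir, sprintf("trace_%s_%snm.csv", id, wl)))
      write_peak_table(sim$truth[[wl]]$tables[[b]],
                       file.path(outdir, sprintf("truth_%s_%snm.csv", id, wl)))
    }
  }
  manifest <- list(
    seed = seed %||% design$seed, n_batches = design$n_batches,
    gradient_end_min = design$gradient_end_min, noise_sd = design$noise_sd,
    wavelengths_nm = design$wavelengths_nm,
    n_common = length(design$common_peaks),
    n_spurious = length(design$spurious_peaks),
    n_solvent = length(design$solvent_peaks),
    common_peaks = lapply(design$common_peaks, unclass),
    spurious_peaks = lapply(design$spurious_peaks, unclass),
    solvent_peaks = lapply(design$solvent_peaks, unclass))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
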