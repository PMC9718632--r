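# Synthetic chromatogram generator.
#
# Downstream stages (detection, matching, fingerprinting, QAMS) are
# validated against panels with known ground truth: Gaussian peaks on a
# 0-130 min gradient, log-normal batch-to-batch area variation, normal
# retention-time jitter, solvent-front peaks before 5 min, sub-threshold
# and intermittent spurious peaks, and two detection channels with
# per-analyte response multipliers.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Gaussian chromatographic peak
#'
#' Standard Gaussian peak model `height * exp(-(t - rt)^2 / (2 sigma^2))`
#' with analytic area `height * sigma * sqrt(2 * pi)`.
#'
#' @param t time grid (minutes).
#' @param rt peak centre (minutes).
#' @param height apex signal.
#' @param sigma peak width standard deviation (minutes, > 0).
#' @return Signal at each `t`.
#' @examples
#' gaussian_peak(10, rt = 10, height = 5, sigma = 0.1)  # apex: 5
#' @export
gaussian_peak <- function(t, rt, height, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_domain("sigma must be > 0")
  height * exp(-(t - rt)^2 / (2 * sigma^2))
}

#' Specify one synthetic peak
#'
#' @param analyte analyte name ("unknown" for anonymous peaks).
#' @param rt_mean_min mean retention time (minutes).
#' @param area_mean mean peak area at the primary (237 nm) channel (> 0).
#' @param area_cv between-batch coefficient of variation of the area
#'   (fraction, >= 0); areas are drawn log-normal so they stay positive.
#' @param rt_jitter_sd_min between-batch retention-time standard deviation
#'   (minutes).
#' @param response_237,response_327 per-channel response multipliers
#'   (>= 0; 0 means no absorption at that wavelength). At least one must be
#'   positive.
#' @param width_sd_min Gaussian peak width sigma (minutes).
#' @param present_frac fraction of batches containing the peak. 1 means
#'   every batch; below 1 the generator places the peak in
#'   `round(frac * n_batches)` randomly chosen batches (at least 1 and, so
#'   that the peak is genuinely intermittent, at most `n_batches - 1`).
#' @param herb_tags character vector of source-herb labels (tagging
#'   convention only).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(analyte = "unknown", rt_mean_min, area_mean,
                      area_cv = 0.08, rt_jitter_sd_min = 0.1,
                      response_237 = 1, response_327 = 0,
                      width_sd_min = 0.1, present_frac = 1,
                      herb_tags = character()) {
  assert_scalar_pos(area_mean, "area_mean")
  if (area_cv < 0) stop_domain("area_cv must be >= 0")
  if (rt_jitter_sd_min < 0) stop_domain("rt_jitter_sd_min must be >= 0")
  if (response_237 < 0 || response_327 < 0)
    stop_domain("responses must be >= 0")
  if (response_237 == 0 && response_327 == 0)
    stop_domain("at least one wavelength response must be > 0")
  assert_scalar_pos(width_sd_min, "width_sd_min")
  if (present_frac <= 0 || present_frac > 1)
    stop_domain("present_frac must be in (0, 1]")
  structure(list(analyte = analyte, rt_mean_min = rt_mean_min,
                 area_mean = area_mean, area_cv = area_cv,
                 rt_jitter_sd_min = rt_jitter_sd_min,
                 response_237 = response_237, response_327 = response_327,
                 width_sd_min = width_sd_min, present_frac = present_frac,
                 herb_tags = herb_tags),
            class = "peak_spec")
}

#' Design a synthetic batch panel
#'
#' @param n_batches number of batches (>= 2).
#' @param common_peaks list of [peak_spec()] objects present in every batch
#'   with retention times inside (5, `gradient_end_min`).
#' @param spurious_peaks list of [peak_spec()] objects that are
#'   sub-threshold in area or present in only a subset of batches.
#' @param solvent_peaks list of [peak_spec()] objects with rt below 5 min
#'   (the solvent front).
#' @param gradient_end_min run length in minutes.
#' @param noise_sd baseline noise standard deviation (signal units).
#' @param drift_per_min linear baseline drift (signal units per minute).
#' @param wavelengths_nm detection channels.
#' @param seed RNG seed; the generator is a pure function of
#'   (design, seed).
#' @return An object of class `panel_design`.
#' @export
panel_design <- function(n_batches = 10, common_peaks, spurious_peaks = list(),
                         solvent_peaks = list(), gradient_end_min = 130,
                         noise_sd = 0.02, drift_per_min = 0,
                         wavelengths_nm = c(237, 327), seed = 1L) {
  if (n_batches < 2) stop_domain("n_batches must be >= 2")
  for (p in common_peaks) {
    if (p$rt_mean_min <= 5 || p$rt_mean_min >= gradient_end_min)
      stop_domain("common peak rt must lie in (5, gradient_end_min): ",
                  p$analyte, " at ", p$rt_mean_min)
  }
  structure(list(n_batches = n_batches, common_peaks = common_peaks,
                 spurious_peaks = spurious_peaks,
                 solvent_peaks = solvent_peaks,
                 gradient_end_min = gradient_end_min, noise_sd = noise_sd,
                 drift_per_min = drift_per_min,
                 wavelengths_nm = wavelengths_nm, seed = as.integer(seed)),
            class = "panel_design")
}

# Marker analytes of the formula, their published calibration lines and the
# mixed-standard concentrations, drive the default design so that detected
# areas invert to realistic contents (mg per g of powder).
marker_rts <- c("neochlorogenic acid" = 16.4, "chlorogenic acid" = 33.2,
                "forsythoside A" = 62.6, "isochlorogenic acid A" = 75.2,
                "isochlorogenic acid C" = 92.0, "phillyrin" = 108.8,
                "arctiin" = 113.0)

#' Default synthetic panel design
#'
#' Emulates a 10-batch quality-control panel of a multi-herb formula:
#' 29 shared supra-threshold peaks between 5 and 130 min (including the
#' seven quantified marker analytes, with phillyrin and arctiin absorbing
#' only at 237 nm), 15 spurious peaks (8 sub-threshold, 7 intermittent),
#' 3 solvent-front peaks before 5 min, 8 % between-batch area CV and
#' 0.1 min retention-time jitter.
#'
#' @param n_batches number of batches.
#' @param area_cv between-batch area coefficient of variation (fraction).
#' @param rt_jitter_sd_min between-batch retention-time jitter (minutes).
#' @param seed RNG seed stored in the design.
#' @return A [panel_design()].
#' @export
default_panel_design <- function(n_batches = 10, area_cv = 0.08,
                                 rt_jitter_sd_min = 0.1, seed = 1L) {
  rts <- 8 + 4.2 * (0:28)              # 8 .. 125.6 min, 4.2 min spacing
  # anonymous-peak areas: reproducible spread over ~0.8-20 area units
  base_areas <- 0.8 + 19.2 * (seq(7, 137, length.out = 29) %% 29) / 29
  labels <- rep("unknown", 29)
  resp327 <- rep(0.6, 29)
  # place the seven markers at their conventional elution positions
  marker_pos <- c("neochlorogenic acid" = 3, "chlorogenic acid" = 7,
                  "forsythoside A" = 14, "isochlorogenic acid A" = 17,
                  "isochlorogenic acid C" = 21, "phillyrin" = 25,
                  "arctiin" = 26)
  # 237-nm areas consistent with typical contents through the published
  # calibration lines; 327-nm response as the area ratio of the channels
  marker_area237 <- c("neochlorogenic acid" = 1.6, "chlorogenic acid" = 14.0,
                      "forsythoside A" = 23.0, "isochlorogenic acid A" = 9.0,
                      "isochlorogenic acid C" = 2.6, "phillyrin" = 2.4,
                      "arctiin" = 12.8)
  marker_resp327 <- c("neochlorogenic acid" = 0.53, "chlorogenic acid" = 2.15,
                      "forsythoside A" = 1.645, "isochlorogenic acid A" = 1.95,
                      "isochlorogenic acid C" = 1.88, "phillyrin" = 0,
                      "arctiin" = 0)
  for (nm in names(marker_pos)) {
    i <- marker_pos[[nm]]
    labels[i] <- nm
    rts[i] <- 8 + 4.2 * (i - 1)
    base_areas[i] <- marker_area237[[nm]]
    resp327[i] <- marker_resp327[[nm]]
  }
  common <- lapply(seq_len(29), function(i)
    peak_spec(labels[i], rt_mean_min = rts[i], area_mean = base_areas[i],
              area_cv = area_cv, rt_jitter_sd_min = rt_jitter_sd_min,
              response_237 = 1, response_327 = resp327[i]))
  # spurious peaks sit midway between common peaks (>= 2 min from any)
  sp_rts <- 10.1 + 4.2 * (0:14)
  spurious <- lapply(seq_len(15), function(i) {
    if (i <= 8) {
      # sub-threshold in every batch: mean area well below the 0.4 screen
      peak_spec("spurious_sub", rt_mean_min = sp_rts[i],
                area_mean = 0.12 + 0.015 * i, area_cv = area_cv,
                rt_jitter_sd_min = rt_jitter_sd_min,
                response_237 = 1, response_327 = 0.5)
    } else {
      # supra-threshold but present in only ~60 % of batches
      peak_spec("spurious_intermittent", rt_mean_min = sp_rts[i],
                area_mean = 1.5 + 0.3 * i, area_cv = area_cv,
                rt_jitter_sd_min = rt_jitter_sd_min,
                response_237 = 1, response_327 = 0.5, present_frac = 0.6)
    }
  })
  solvent <- lapply(c(1.2, 2.5, 3.8), function(rt)
    peak_spec("solvent", rt_mean_min = rt, area_mean = 12, area_cv = area_cv,
              rt_jitter_sd_min = 0.02, response_237 = 1, response_327 = 1,
              width_sd_min = 0.08))
  panel_design(n_batches = n_batches, common_peaks = common,
               spurious_peaks = spurious, solvent_peaks = solvent,
               gradient_end_min = 130, noise_sd = 0.02,
               wavelengths_nm = c(237, 327), seed = seed)
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic batch panel with ground truth
#'
#' For every batch and wavelength, synthesises a raw chromatogram trace
#' (sum of Gaussian peaks plus baseline noise and optional drift) and the
#' exact ground-truth peak table. Per batch, each peak's retention time is
#' jittered `Normal(rt_mean, rt_jitter_sd)` and its base area drawn
#' log-normal at the stated CV; the same draw is shared across wavelengths
#' (one injection) and scaled by the per-channel response multiplier.
#' Fully reproducible given the seed.
#'
#' @param design a [panel_design()].
#' @param seed overrides `design$seed` when given.
#' @param traces set `FALSE` to skip trace synthesis (ground-truth tables
#'   only; much faster for matching-level studies).
#' @param dt_min trace grid step in minutes.
#' @return A list with `traces` (per wavelength, a list of [chrom_trace()]
#'   per batch; `NULL` when `traces = FALSE`), `truth` (per wavelength, a
#'   [batch_panel()] of exact peak tables) and `design`.
#' @export
make_batch_panel <- function(design, seed = NULL, traces = TRUE,
                             dt_min = 0.01) {
  stopifnot(inherits(design, "panel_design"))
  seed <- seed %||% design$seed
  specs <- c(design$solvent_peaks, design$common_peaks, design$spurious_peaks)
  n_b <- design$n_batches
  n_p <- length(specs)
  # resolution warning: common peaks closer than 4 sigma
  crts <- vapply(design$common_peaks, `[[`, numeric(1), "rt_mean_min")
  csig <- vapply(design$common_peaks, `[[`, numeric(1), "width_sd_min")
  if (length(crts) > 1L) {
    o <- order(crts)
    gap <- diff(crts[o]); lim <- 2 * (csig[o][-1] + csig[o][-length(csig)])
    if (any(gap < lim))
      warning("common peaks closer than 4 sigma: resolution below 1.5 emulated")
  }
  with_seed(seed, {
    rt_draw <- matrix(NA_real_, n_b, n_p)
    area_draw <- matrix(NA_real_, n_b, n_p)
    present <- matrix(TRUE, n_b, n_p)
    for (j in seq_len(n_p)) {
      sp <- specs[[j]]
      rt_draw[, j] <- stats::rnorm(n_b, sp$rt_mean_min, sp$rt_jitter_sd_min)
      area_draw[, j] <- sp$area_mean * lognormal_factor(n_b, sp$area_cv)
      if (sp$present_frac < 1) {
        k <- max(1L, min(n_b - 1L, round(sp$present_frac * n_b)))
        present[, j] <- FALSE
        present[sample.int(n_b, k), j] <- TRUE
      }
    }
    out <- list(traces = NULL, truth = list(), design = design)
    grid <- seq(0, design$gradient_end_min + 1, by = dt_min)
    for (wl in design$wavelengths_nm) {
      resp <- vapply(specs, function(sp)
        if (wl == 327) sp$response_327 else sp$response_237, numeric(1))
      tables <- vector("list", n_b)
      wtr <- vector("list", n_b)
      for (b in seq_len(n_b)) {
        keep <- which(present[b, ] & resp > 0)
        keep <- keep[order(rt_draw[b, keep])]
        areas_b <- area_draw[b, keep] * resp[keep]
        tables[[b]] <- peak_table(
          sample_id = sprintf("B%02d", b), wavelength_nm = wl,
          rt_min = rt_draw[b, keep], area = areas_b,
          height = areas_b / (vapply(specs[keep], `[[`, numeric(1),
                                     "width_sd_min") * sqrt(2 * pi)),
          label = vapply(specs[keep], `[[`, character(1), "analyte"))
        if (traces) {
          y <- numeric(length(grid))
          for (kk in seq_along(keep)) {
            j <- keep[kk]
            sg <- specs[[j]]$width_sd_min
            h <- areas_b[kk] / (sg * sqrt(2 * pi))
            rt <- rt_draw[b, j]
            win <- which(grid >= rt - 6 * sg & grid <= rt + 6 * sg)
            y[win] <- y[win] + gaussian_peak(grid[win], rt, h, sg)
          }
          if (design$noise_sd > 0)
            y <- y + stats::rnorm(length(grid), 0, design$noise_sd)
          if (design$drift_per_min != 0)
            y <- y + design$drift_per_min * grid
          wtr[[b]] <- chrom_trace(grid, y, wl)
        }
      }
      names(tables) <- vapply(tables, attr, character(1), "sample_id")
      out$truth[[as.character(wl)]] <- batch_panel(tables)
      if (traces) {
        names(wtr) <- names(tables)
        out$traces[[as.character(wl)]] <- wtr
      }
    }
    out
  })
}

#' Simulate an external-standard calibration series
#'
#' `area = slope * amount + intercept`, multiplied by
#' `(1 + Normal(0, noise_cv))`; `noise_cv = 0` gives the exact line.
#' Amounts outside the stated linear range are flagged with a warning, not
#' dropped.
#'
#' @param slope,intercept calibration line (area per microgram; area).
#' @param amounts_ug amounts injected (micrograms).
#' @param noise_cv multiplicative noise CV (fraction).
#' @param linear_range_ug optional `c(low, high)` linear range.
#' @param seed RNG seed.
#' @return Data frame with `amount_ug`, `area`, `in_range`.
#' @export
make_calibration_series <- function(slope, intercept, amounts_ug,
                                    noise_cv = 0, linear_range_ug = NULL,
                                    seed = NULL) {
  area <- slope * amounts_ug + intercept
  if (noise_cv > 0)
    area <- with_seed(seed, area * (1 + stats::rnorm(length(area), 0, noise_cv)))
  in_range <- rep(TRUE, length(amounts_ug))
  if (!is.null(linear_range_ug)) {
    in_range <- amounts_ug >= linear_range_ug[1] & amounts_ug <= linear_range_ug[2]
    if (any(!in_range))
      warning("amount(s) outside the linear range flagged: ",
              paste(amounts_ug[!in_range], collapse = ", "))
  }
  data.frame(amount_ug = amounts_ug, area = area, in_range = in_range)
}

#' Simulate spike-recovery experiments
#'
#' `detected = original + spike * efficiency * (1 + Normal(0, noise_cv))`;
#' the ground-truth recovery of each replicate is returned alongside.
#'
#' @param original_content original amount in the sample (any consistent
#'   unit).
#' @param spike_levels amounts spiked (> 0), one replicate per element.
#' @param efficiency true recovery fraction, in (0, 1.5].
#' @param noise_cv replicate noise CV (fraction).
#' @param seed RNG seed.
#' @return Data frame with `original`, `spiked`, `detected`,
#'   `true_recovery_pct`.
#' @export
make_recovery_samples <- function(original_content, spike_levels,
                                  efficiency = 1, noise_cv = 0, seed = NULL) {
  if (any(spike_levels <= 0)) stop_domain("spike levels must be > 0")
  if (efficiency <= 0 || efficiency > 1.5)
    stop_domain("efficiency must be in (0, 1.5]")
  eff <- efficiency
  if (noise_cv > 0)
    eff <- with_seed(seed,
      efficiency * (1 + stats::rnorm(length(spike_levels), 0, noise_cv)))
  detected <- original_content + spike_levels * eff
  data.frame(original = original_content, spiked = spike_levels,
             detected = detected, true_recovery_pct = 100 * eff)
}
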