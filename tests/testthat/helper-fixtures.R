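# Small builders shared across test files.

tiny_table <- function(id = "S1", wl = 237, rt = c(6, 12, 20),
                       area = c(1, 2, 3), label = NULL) {
  peak_table(id, wl, rt_min = rt, area = area, label = label)
}

# a noiseless panel design with three well-separated common peaks
mini_design <- function(n_batches = 3, area_cv = 0, jitter = 0,
                        noise = 0, seed = 1) {
  panel_design(
    n_batches = n_batches,
    common_peaks = list(
      peak_spec("a", 10, 5, area_cv = area_cv, rt_jitter_sd_min = jitter,
                response_327 = 0.5),
      peak_spec("b", 20, 2, area_cv = area_cv, rt_jitter_sd_min = jitter,
                response_327 = 1),
      peak_spec("c", 30, 8, area_cv = area_cv, rt_jitter_sd_min = jitter,
                response_327 = 0)),
    gradient_end_min = 40, noise_sd = noise, seed = seed)
}

# detection-free run of the matching stage on ground-truth tables
match_truth <- function(sim, wl = "237", cfg = match_config()) {
  sheared <- lapply(sim$truth[[wl]]$tables, shear_solvent_region,
                    cut_min = cfg$solvent_cut_min)
  match_common_peaks(batch_panel(sheared), cfg)
}
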