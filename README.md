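# qamsfp

Quality evaluation of multi-herb preparations from dual-wavelength HPLC
data: chromatographic fingerprinting with median-reference similarity
scoring, multivariate key-component screening (PCA, PLS-DA/VIP), and
single-marker quantitation (QAMS) with relative correction factors,
validated against external-standard calibration and spike recovery.

The package targets analysts doing pharmacopoeial-style batch QC of
herbal formulas (the packaged reference data come from a published
dual-wavelength study of Yinqiao powder) and methods developers who
need a fully synthetic, ground-truth-known test bed for fingerprint
pipelines.

## What it computes

* **Fingerprint**: peaks are detected from raw traces (Savitzky–Golay
  smoothing, prominence-filtered maxima, valley-to-valley trapezoidal
  integration with linear baseline), the solvent front (< 5 min) is
  sheared, peaks are matched across batches within a retention-time
  tolerance, and only peaks present in *every* batch with area
  strictly > 0.4 survive. The reference fingerprint is the per-peak
  median over batches; each batch is scored with the included-angle
  cosine `S = Σ aᵢrᵢ / (‖a‖‖r‖)`.
* **Screening**: correlation-matrix PCA (eigenvalues, variance
  contributions, component loadings `v√λ`, scree data) and NIPALS
  PLS-DA with variable importance
  `VIPⱼ = √(p · Σₐ SSₐ wₐⱼ² / Σₐ SSₐ)`; peaks with VIP > 1 are key
  components.
* **Quantitation**: external-standard contents via
  `amount = (area − b)/k` and the 0.5 g / 25 mL / 5 µL preparation
  constants; relative correction factors
  `f_x = (W_is·A_x)/(W_x·A_is)`; single-marker contents
  `c_x = A_x·c_is/(f_x·A_is)`; recovery rates and QAMS-vs-ESM relative
  errors.

A synthetic chromatogram generator (`default_panel_design()`,
`make_batch_panel()`) emulates the 10-batch, 29-common-peak,
two-channel study design with known ground truth, so the whole
pipeline is testable without instrument data.

## Worked example

```r
library(qamsfp)
bundle <- run_pipeline(pipeline_config(seed = 1))

length(bundle$matrix$peak_ids)
#> [1] 29
round(bundle$similarities, 4)
#>    B01    B02    B03    B04    B05    B06    B07    B08    B09    B10
#> 0.9976 0.9973 0.9987 0.9959 0.9944 0.9981 0.9954 0.9984 0.9971 0.9965
bundle$pca$n_nonzero
#> [1] 9
bundle$rcfs[, c("analyte", "wavelength_nm", "f")]
#>                 analyte wavelength_nm         f
#> 1   neochlorogenic acid           327 2.1936989
#> 2      chlorogenic acid           327 1.6122856
#> 3 isochlorogenic acid A           327 1.5529592
#> 4 isochlorogenic acid C           327 1.7875928
#> 5             phillyrin           237 0.8373856
#> 6               arctiin           237 0.8656466
```

Reading: all 29 planted common peaks were recovered from the simulated
traces; every batch scores ≳ 0.99 against the median reference (the
conventional acceptance bound is 0.95); ten batches of 29 peaks span
exactly 9 principal components (rank n − 1); and the correction
factors derived from the packaged calibration lines sit within ~1 % of
the published means (e.g. phillyrin 0.837 vs 0.838), as they should,
since both derive from the same detector responses.

The per-batch content report is in `bundle$contents`; for batch 1,
phillyrin comes out at 1.098 mg·g⁻¹ by ESM and 1.099 mg·g⁻¹ by QAMS
(relative error 0.06 %).

The published study tables are packaged and can be re-analysed
directly:

```r
out <- recompute_reference_report()
c(out$summary$min_re_pct, out$summary$max_re_pct)
#> [1] -0.83  1.08
```

## Layout

* `R/` — implementation (data containers and CSV I/O, synthetic
  generator, peak processing, fingerprint similarity, multivariate QC,
  QAMS, pipeline).
* `inst/extdata/` — packaged study tables (calibration lines,
  correction-factor replicates, batch contents, standard-mix
  concentrations).
* `inst/cli/qamsfp.R` — thin command-line wrapper (`simulate`, `run`).
* `vignettes/qamsfp-methods.Rmd` — the methods vignette: models,
  conventions, generator assumptions, limitations.
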