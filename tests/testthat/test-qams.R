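test_that("calibration fitting recovers exact lines and matches the normal equations", {
  amounts <- seq(0.1776, 2.96, length.out = 6)
  ser <- make_calibration_series(26.30, 0.073, amounts)
  cv <- fit_calibration(ser$amount_ug, ser$area, "forsythoside A", 237)
  expect_equal(cv$slope, 26.30, tolerance = 1e-9)
  expect_equal(cv$intercept, 0.073, tolerance = 1e-9)
  expect_equal(cv$r, 1, tolerance = 1e-9)
  expect_equal(cv$linear_range_ug, range(amounts))

  # two points: exact interpolating line
  cv2 <- fit_calibration(c(1, 2), c(10, 18))
  expect_equal(cv2$slope, 8)
  expect_equal(cv2$intercept, 2)

  # noisy series vs brute-force normal equations
  for (seed in 1:5) {
    set.seed(seed)
    x <- seq(0.1, 1, length.out = 8)
    y <- 5 * x + 0.3 + rnorm(8, 0, 0.05)
    cf <- fit_calibration(x, y)
    beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
    expect_equal(cf$intercept, beta[1], tolerance = 1e-10)
    expect_equal(cf$slope, beta[2], tolerance = 1e-10)
  }
  expect_error(fit_calibration(1, 2), "at least 2")
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("external-standard content applies the prep conversion", {
  cv <- calibration_curve(26.30, 0.073, linear_range_ug = c(0.1776, 2.96))
  # 1 ug on column with 0.5 g / 25 mL / 5 uL: 10 mg per g
  expect_equal(esm_content(26.373, cv), 10)
  expect_equal(esm_content(cv$intercept + cv$slope * 0.2, cv), 2)
  expect_warning(esm_content(0.073, cv), "linear range")  # 0 ug, below range
  # published batch content inverts to an on-column amount inside the range
  amount <- 8.689 * 0.5 * 1000 / (25 * 1000 / 5) / 1  # mg/g -> ug on column
  expect_equal(amount, 0.869, tolerance = 1e-3)
  expect_gt(amount, 0.1776)
  expect_lt(amount, 2.96)
  expect_error(esm_content(1, calibration_curve(-1, 0)), "slope")
})

test_that("content recovery through the forward response is exact", {
  cv <- calibration_curve(43.42, 0.065, linear_range_ug = c(0.1776, 2.96))
  prep <- sample_prep()
  for (content in c(2, 5, 10, 25)) {
    amount <- content * prep$sample_mass_g * 1000 /
      (prep$extract_volume_mL * 1000 / prep$injection_volume_uL)
    area <- cv$slope * amount + cv$intercept
    expect_equal(suppressWarnings(esm_content(area, cv, prep)), content,
                 tolerance = 1e-9)
  }
})

test_that("relative correction factor follows its definition and invariances", {
  expect_equal(rcf(W_is = 3, A_is = 7, W_x = 3, A_x = 7), 1)
  expect_equal(rcf(296, 100, 27.5, 7.79), 0.8385, tolerance = 1e-4)
  for (seed in 1:10) {
    set.seed(seed)
    w <- runif(2, 1, 100); a <- runif(2, 1, 50)
    k <- runif(1, 0.1, 10); j <- runif(1, 0.1, 10)
    expect_equal(rcf(w[1], k * a[1], w[2], k * a[2]),
                 rcf(w[1], a[1], w[2], a[2]))
    expect_equal(rcf(j * w[1], a[1], j * w[2], a[2]),
                 rcf(w[1], a[1], w[2], a[2]))
  }
  expect_error(rcf(1, 0, 1, 1), "positive")
})

test_that("replicate aggregation reproduces the published means", {
  reps <- ref_rcf_replicates()
  means <- ref_rcf_means()
  for (i in seq_len(nrow(means))) {
    f <- reps$f[reps$analyte == means$analyte[i] &
                  reps$wavelength_nm == means$wavelength_nm[i]]
    agg <- aggregate_rcf(f, means$analyte[i], means$wavelength_nm[i])
    expect_equal(agg$mean_reported, means$mean_f[i],
                 info = means$analyte[i])
  }
  expect_equal(aggregate_rcf(c(2, 2, 2))$rsd_pct, 0)
  expect_error(aggregate_rcf(1.5), "at least 2")
})

test_that("cross-condition reproducibility check flags deviating analytes", {
  sets <- data.frame(analyte = rep(c("x", "y"), each = 3),
                     wavelength_nm = 237,
                     mean_f = c(1.00, 1.00, 1.00, 1.00, 1.10, 0.90))
  out <- check_rcf_reproducibility(sets, max_rsd_pct = 3)
  expect_true(out$pass[out$analyte == "x"])
  expect_equal(out$rsd_pct[out$analyte == "x"], 0)
  expect_false(out$pass[out$analyte == "y"])
  expect_warning(
    check_rcf_reproducibility(
      data.frame(analyte = c("x", "x", "z"), wavelength_nm = 237,
                 mean_f = c(1, 1, 1))),
    "skipped")
})

test_that("single-marker content matches hand values and the zero-intercept identity", {
  expect_equal(qams_content(A_x = 50, f_x = 1, A_is = 50, is_content = 2), 2)
  expect_equal(qams_content(25, 0.5, 50, 2.0), 2.0)
  expect_error(qams_content(1, 0, 1, 1), "positive")

  # zero intercepts + correction factor from the same calibration data
  # make QAMS identical to ESM for every analyte/wavelength pair
  prep <- sample_prep()
  lines <- ref_calibration_lines()
  lines$intercept <- 0
  mix <- ref_standard_mix()
  for (wl in c(237, 327)) {
    li <- lines[lines$wavelength_nm == wl, ]
    is_row <- li[li$analyte == "forsythoside A", ]
    W_is <- mix$conc_ug_ml[mix$analyte == "forsythoside A"]
    A_is_std <- is_row$slope * W_is * prep$injection_volume_uL / 1000
    is_curve <- calibration_curve(is_row$slope, 0)
    A_is_sample <- 20
    is_content <- suppressWarnings(esm_content(A_is_sample, is_curve, prep))
    for (an in setdiff(li$analyte, "forsythoside A")) {
      row <- li[li$analyte == an, ]
      W_x <- mix$conc_ug_ml[mix$analyte == an]
      A_x_std <- row$slope * W_x * prep$injection_volume_uL / 1000
      f <- rcf(W_is, A_is_std, W_x, A_x_std)
      A_x_sample <- 7.3
      esm <- suppressWarnings(esm_content(
        A_x_sample, calibration_curve(row$slope, 0), prep))
      qams <- qams_content(A_x_sample, f, A_is_sample, is_content)
      expect_equal(qams, esm, tolerance = 1e-10, info = paste(an, wl))
    }
  }
})

test_that("recovery rate and relative error match their closed forms", {
  expect_equal(recovery_rate(20, 10, 10), 100)
  expect_equal(recovery_rate(10, 10, 10), 0)
  expect_equal(recovery_rate(19.6, 10, 10), 96)
  expect_error(recovery_rate(1, 1, 0), "positive")

  expect_equal(relative_error(0.862, 0.868, digits = 2), -0.69)
  expect_equal(relative_error(0.094, 0.093, digits = 2), 1.08)
  expect_equal(relative_error(5, 5), 0)
  expect_error(relative_error(1, 0), "positive")
  # antisymmetric to first order
  expect_equal(relative_error(1.001, 1), -relative_error(0.999, 1),
               tolerance = 1e-3)
})

test_that("re_summary reports extrema and per-analyte ranges", {
  rep1 <- data.frame(analyte = c("a", "a", "b"), re_pct = c(-0.5, 0.3, 1.2))
  s <- re_summary(rep1)
  expect_equal(s$min_re_pct, -0.5)
  expect_equal(s$max_re_pct, 1.2)
  expect_equal(s$by_analyte$max_re_pct[s$by_analyte$analyte == "a"], 0.3)
  single <- re_summary(data.frame(re_pct = 0.7))
  expect_equal(single$min_re_pct, single$max_re_pct)
  perm <- re_summary(rep1[c(3, 1, 2), ])
  expect_equal(perm$min_re_pct, s$min_re_pct)
  expect_equal(perm$max_re_pct, s$max_re_pct)
})

test_that("half-up rounding follows the reporting convention", {
  expect_equal(round_half_up(0.8375, 3), 0.838)
  expect_equal(round_half_up(-0.695, 2), -0.70)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(c(1.005, -1.005), 2), c(1.01, -1.01))
})
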