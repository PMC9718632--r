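test_that("detection on flat or short traces behaves per contract", {
  t <- seq(0, 10, 0.01)
  expect_equal(nrow(detect_peaks(chrom_trace(t, rep(0, length(t)), 237))), 0L)
  expect_error(detect_peaks(chrom_trace(c(0, 1), c(0, 0), 237)),
               "at least 3")
  expect_error(detect_peaks(chrom_trace(t, rep(0, length(t)), 237),
                            min_height = -1), ">= 0")
})

test_that("detection recovers a planted Gaussian's rt and area", {
  t <- seq(0, 2, 0.001)
  tr <- chrom_trace(t, gaussian_peak(t, 1, 10, 0.05), 237)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$rt_min - 1), 0.0015)
  expect_equal(pk$area, 1.2533, tolerance = 0.02)
})

test_that("detection resolves two separated Gaussians", {
  t <- seq(0, 4, 0.001)
  y <- gaussian_peak(t, 1, 10, 0.05) + gaussian_peak(t, 2, 4, 0.05)
  pk <- detect_peaks(chrom_trace(t, y, 237))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$rt_min, c(1, 2), tolerance = 0.005)
  expect_equal(pk$area, c(10, 4) * 0.05 * sqrt(2 * pi), tolerance = 0.02)
})

test_that("solvent shearing removes strictly-before-cut peaks only", {
  tb <- tiny_table(rt = c(3, 5, 6), area = c(1, 1, 1))
  sheared <- shear_solvent_region(tb, 5)
  expect_equal(sheared$rt_min, c(5, 6))  # boundary peak retained
  expect_equal(shear_solvent_region(tb, 0)$rt_min, tb$rt_min)
  expect_error(shear_solvent_region(tb, -1), ">= 0")
})

test_that("area screening is strictly greater-than", {
  tb <- tiny_table(rt = c(6, 7, 8), area = c(0.3, 0.4, 0.5))
  expect_equal(filter_min_area(tb, 0.4)$area, 0.5)
  expect_equal(nrow(filter_min_area(tb, 0)), 3L)
  m <- common_peak_matrix(c("a", "b"), c(6, 7),
                          rbind(c(0.41, 2), c(0.39, 3)))
  expect_equal(length(filter_min_area(m, 0.4)$peak_ids), 1L)
})

test_that("shear and area screen commute on peak tables", {
  for (seed in 1:10) {
    set.seed(seed)
    tb <- peak_table("S", 237, rt_min = sort(runif(20, 0, 30)),
                     area = runif(20, 0, 2))
    a <- filter_min_area(shear_solvent_region(tb, 5), 0.4)
    b <- shear_solvent_region(filter_min_area(tb, 0.4), 5)
    expect_equal(a$rt_min, b$rt_min)
    expect_equal(a$area, b$area)
  }
})

test_that("identical batches make every peak common", {
  tabs <- lapply(c("a", "b", "c"), tiny_table)
  m <- match_common_peaks(batch_panel(tabs), match_config(min_area = 0))
  expect_equal(length(m$peak_ids), 3L)
  expect_true(all(apply(m$areas, 2, function(col) length(unique(col)) == 1)))
  expect_equal(m$consensus_rt_min, c(6, 12, 20))
})

test_that("a peak absent from one batch is not a common peak", {
  tabs <- c(lapply(c("a", "b", "c"), tiny_table),
            list(tiny_table("d", rt = c(6, 20), area = c(1, 3))))
  m <- match_common_peaks(batch_panel(tabs), match_config(min_area = 0))
  expect_equal(length(m$peak_ids), 2L)
  expect_equal(m$consensus_rt_min, c(6, 20))
})

test_that("matching errors on an empty batch, naming it", {
  tabs <- list(tiny_table("a"), peak_table("b", 237, numeric(0), numeric(0)))
  expect_error(match_common_peaks(batch_panel(tabs)), "b")
})

test_that("ground truth is recovered exactly across seeds and batch orders", {
  cfg <- match_config(rt_tolerance_min = 0.5, min_area = 0.4)
  for (seed in 1:50) {
    sim <- make_batch_panel(default_panel_design(seed = seed),
                            traces = FALSE)
    m <- match_truth(sim, cfg = cfg)
    expect_equal(length(m$peak_ids), 29L)
  }
  # permutation invariance of the matched set (up to relabeling)
  sim <- make_batch_panel(default_panel_design(seed = 123), traces = FALSE)
  sheared <- lapply(sim$truth[["237"]]$tables, shear_solvent_region)
  m1 <- match_common_peaks(batch_panel(sheared), cfg)
  perm <- c(4, 1, 10, 3, 2, 7, 5, 9, 8, 6)
  m2 <- match_common_peaks(batch_panel(sheared[perm]), cfg)
  expect_equal(m1$consensus_rt_min, m2$consensus_rt_min, tolerance = 1e-12)
  expect_equal(m1$areas[perm, ], unname(m2$areas), ignore_attr = TRUE)
})

test_that("relative-retention localization picks the nearest in-tolerance peak", {
  tb <- tiny_table(rt = c(11.0, 13.0), area = c(1, 5))
  # rrv 1.10 vs 1.30, expected 1.12, tol 5 %: 1.10 wins despite smaller area
  hit <- locate_by_relative_retention(tb, is_rt = 10, expected_rrv = 1.12,
                                      tol = 0.05)
  expect_equal(hit$rt_min, 11.0)
  exact <- locate_by_relative_retention(tb, 10, 1.3, tol = 0.01)
  expect_equal(exact$rt_min, 13.0)
  expect_error(
    locate_by_relative_retention(tb, 10, 2.0, tol = 0.01),
    "nearest candidate")
  expect_error(locate_by_relative_retention(
    peak_table("e", 237, numeric(0), numeric(0)), 10, 1.1), "no peaks")
})

test_that("rt-difference localization breaks ties toward the larger area", {
  tb <- tiny_table(rt = c(14, 18), area = c(2, 9))
  # both 2 min from the expected difference of 6: larger area wins
  hit <- locate_by_rt_difference(tb, is_rt = 10, expected_delta = 6, tol = 3)
  expect_equal(hit$rt_min, 18)
  expect_equal(locate_by_rt_difference(tb, 10, 4, tol = 0.1)$rt_min, 14)
  expect_error(locate_by_rt_difference(tb, 10, 30, tol = 1), "no peak")
})
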