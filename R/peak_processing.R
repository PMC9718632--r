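# Peak detection and cross-batch common-peak matching.

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Matching configuration
#'
#' Holds the cross-batch matching constants: the retention-time window,
#' the common-peak area screen (strict `area > min_area`), the
#' solvent-front cut (strict `rt < solvent_cut_min` removed), and whether
#' a common peak must be present in every batch.
#'
#' @param rt_tolerance_min absolute retention-time matching window
#'   (minutes, > 0).
#' @param min_area area screening threshold (arbitrary detector units).
#' @param solvent_cut_min solvent-front exclusion boundary (minutes).
#' @param require_all_batches must a common peak match in every batch?
#' @param reference_batch index of the batch that seeds the clusters.
#' @return An object of class `match_config`.
#' @export
match_config <- function(rt_tolerance_min = 0.5, min_area = 0.4,
                         solvent_cut_min = 5, require_all_batches = TRUE,
                         reference_batch = 1L) {
  assert_scalar_pos(rt_tolerance_min, "rt_tolerance_min")
  if (min_area < 0) stop_domain("min_area must be >= 0")
  if (solvent_cut_min < 0) stop_domain("solvent_cut_min must be >= 0")
  structure(list(rt_tolerance_min = rt_tolerance_min, min_area = min_area,
                 solvent_cut_min = solvent_cut_min,
                 require_all_batches = isTRUE(require_all_batches),
                 reference_batch = as.integer(reference_batch)),
            class = "match_config")
}

peak_prominence <- function(y, idx) {
  # classical prominence: height above the highest of the two key saddles
  vapply(idx, function(i) {
    h <- y[i]
    left_min <- h
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > h) break
      if (y[j] < left_min) left_min <- y[j]
    }
    if (j == 1L && y[j] <= h && y[j] < left_min) left_min <- y[j]
    right_min <- h
    j <- i
    n <- length(y)
    while (j < n) {
      j <- j + 1L
      if (y[j] > h) break
      if (y[j] < right_min) right_min <- y[j]
    }
    if (j == n && y[j] <= h && y[j] < right_min) right_min <- y[j]
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect peaks in a raw chromatogram
#'
#' Local maxima of the (Savitzky-Golay smoothed) signal above `min_height`
#' and `min_prominence` are taken as apexes; the retention time is the
#' apex grid time. Each peak's area is obtained by trapezoidal integration
#' of the raw signal between flanking boundaries after subtracting a
#' linear baseline drawn between them. A boundary is the first point,
#' walking outward from the apex, where the smoothed signal falls below a
#' gate (`max(0.002 x apex height, 4 x estimated noise)`), capped at the
#' local minimum separating the peak from its neighbour.
#'
#' @param trace a [chrom_trace()].
#' @param min_height minimum apex signal.
#' @param min_prominence minimum apex prominence.
#' @param sample_id sample identifier for the resulting table.
#' @return A [peak_table()]; empty when nothing exceeds the thresholds.
#' @export
detect_peaks <- function(trace, min_height = 0.15, min_prominence = 0.1,
                         sample_id = "sample") {
  stopifnot(inherits(trace, "trace"))
  if (min_height < 0 || min_prominence < 0)
    stop_domain("thresholds must be >= 0")
  t <- trace$time_min
  y <- trace$signal
  n <- length(y)
  if (n < 3L) stop_domain("trace must have at least 3 points")

  sm <- y
  if (n >= 11L) {
    sm <- tryCatch(signal::sgolayfilt(y, p = 3, n = 9), error = function(e) y)
  }
  noise <- 1.4826 * stats::median(abs(diff(y))) / sqrt(2)

  cand <- which(sm[-c(1L, n)] > sm[-c(n - 1L, n)] &
                  sm[-c(1L, n)] >= sm[-c(1L, 2L)]) + 1L
  cand <- cand[sm[cand] >= min_height]
  if (length(cand)) {
    prom <- peak_prominence(sm, cand)
    cand <- cand[prom >= min_prominence]
  }
  if (!length(cand)) {
    return(peak_table(sample_id, trace$wavelength_nm,
                      rt_min = numeric(0), area = numeric(0)))
  }
  cand <- sort(cand)
  k <- length(cand)
  rts <- t[cand]
  heights <- y[cand]
  areas <- numeric(k)
  for (i in seq_len(k)) {
    apex <- cand[i]
    gate <- max(0.002 * sm[apex], 4 * noise)
    # hard limits: valley minima towards the neighbouring apexes
    left_lim <- if (i == 1L) 1L else {
      rng <- cand[i - 1L]:apex
      rng[which.min(sm[rng])]
    }
    right_lim <- if (i == k) n else {
      rng <- apex:cand[i + 1L]
      rng[which.min(sm[rng])]
    }
    L <- apex
    while (L > left_lim && sm[L] > gate) L <- L - 1L
    R <- apex
    while (R < right_lim && sm[R] > gate) R <- R + 1L
    if (R - L < 2L) { L <- max(1L, apex - 1L); R <- min(n, apex + 1L) }
    idx <- L:R
    baseline <- sm[L] + (sm[R] - sm[L]) * (t[idx] - t[L]) / (t[R] - t[L])
    areas[i] <- max(0, trapz(t[idx], y[idx] - baseline))
  }
  keep <- areas > 0
  peak_table(sample_id, trace$wavelength_nm, rt_min = rts[keep],
             area = areas[keep], height = heights[keep])
}

#' Remove the solvent-front region of a peak table
#'
#' Peaks with `rt_min` strictly below `cut_min` are removed; a peak
#' sitting exactly on the boundary is retained.
#'
#' @param table a [peak_table()].
#' @param cut_min exclusion boundary (minutes, >= 0).
#' @return The sheared [peak_table()].
#' @export
shear_solvent_region <- function(table, cut_min = 5) {
  stopifnot(inherits(table, "peak_table"))
  if (cut_min < 0) stop_domain("cut_min must be >= 0")
  keep <- table$rt_min >= cut_min
  subset_peak_table(table, keep)
}

subset_peak_table <- function(table, keep) {
  peak_table(attr(table, "sample_id"), attr(table, "wavelength_nm"),
             rt_min = table$rt_min[keep], area = table$area[keep],
             height = table$height[keep], label = table$label[keep])
}

#' Screen peaks or common-peak columns by minimum area
#'
#' Keeps entries with area strictly greater than `min_area`: per peak for
#' a [peak_table()]; for a [common_peak_matrix()] a column survives only
#' if it exceeds the threshold in every batch.
#'
#' @param x a [peak_table()] or [common_peak_matrix()].
#' @param min_area screening threshold (>= 0).
#' @return Same class as `x`.
#' @export
filter_min_area <- function(x, min_area = 0.4) UseMethod("filter_min_area")

#' @export
filter_min_area.peak_table <- function(x, min_area = 0.4) {
  if (min_area < 0) stop_domain("min_area must be >= 0")
  subset_peak_table(x, x$area > min_area)
}

#' @export
filter_min_area.common_peak_matrix <- function(x, min_area = 0.4) {
  if (min_area < 0) stop_domain("min_area must be >= 0")
  keep <- apply(x$areas, 2L, function(col) all(!is.na(col) & col > min_area))
  common_peak_matrix(x$batch_ids, x$consensus_rt_min[keep],
                     x$areas[, keep, drop = FALSE],
                     rts = if (!is.null(x$rts)) x$rts[, keep, drop = FALSE],
                     wavelength_nm = x$wavelength_nm)
}

greedy_assign <- function(center_rt, peak_rt, tol) {
  # one-to-one nearest-rt assignment of a batch's peaks to cluster centers
  if (!length(center_rt) || !length(peak_rt)) return(integer(length(center_rt)))
  d <- abs(outer(center_rt, peak_rt, "-"))
  pairs <- which(d <= tol, arr.ind = TRUE)
  assign <- integer(length(center_rt))
  if (!nrow(pairs)) return(assign)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_peak <- logical(length(peak_rt))
  for (r in seq_len(nrow(pairs))) {
    ci <- pairs[r, 1L]; pi <- pairs[r, 2L]
    if (assign[ci] == 0L && !used_peak[pi]) {
      assign[ci] <- pi
      used_peak[pi] <- TRUE
    }
  }
  assign
}

#' Match common peaks across the batches of a panel
#'
#' Greedy nearest-rt clustering seeded from the reference batch: every
#' reference peak opens a cluster; each other batch contributes its
#' nearest unassigned peak within `rt_tolerance_min` of the cluster
#' centre. Two refinement passes then re-assign all batches against the
#' consensus (median member) retention times, which makes the window
#' operate around the cross-batch consensus rather than a single jittered
#' reference chromatogram. A cluster is a common peak iff it has exactly
#' one member from every batch (when `require_all_batches`) and its area
#' exceeds `cfg$min_area` in every batch. Columns are ordered by
#' consensus retention time and numbered in elution order.
#'
#' @param panel a [batch_panel()] (all tables already sheared as desired).
#' @param cfg a [match_config()].
#' @return A [common_peak_matrix()].
#' @export
match_common_peaks <- function(panel, cfg = match_config()) {
  stopifnot(inherits(panel, "batch_panel"), inherits(cfg, "match_config"))
  nb <- length(panel$tables)
  empty <- vapply(panel$tables, nrow, integer(1)) == 0L
  if (any(empty))
    stop_domain("empty batch in panel: ",
                paste(panel$batch_ids[empty], collapse = ", "))
  tol <- cfg$rt_tolerance_min
  ref <- cfg$reference_batch
  if (ref < 1L || ref > nb) stop_domain("reference_batch out of range")
  rt_list <- lapply(panel$tables, function(tb) tb$rt_min)
  area_list <- lapply(panel$tables, function(tb) tb$area)

  # pass 1: seed from the reference batch, assign other batches greedily
  centers <- rt_list[[ref]]
  members <- matrix(NA_integer_, nb, length(centers))
  members[ref, ] <- seq_along(centers)
  member_rts <- matrix(NA_real_, nb, length(centers))
  member_rts[ref, ] <- centers
  for (b in setdiff(seq_len(nb), ref)) {
    cons <- apply(member_rts, 2L, stats::median, na.rm = TRUE)
    a <- greedy_assign(cons, rt_list[[b]], tol)
    hit <- a > 0L
    members[b, hit] <- a[hit]
    member_rts[b, hit] <- rt_list[[b]][a[hit]]
  }
  # refinement: re-assign every batch against the consensus rts
  for (pass in 1:2) {
    cons <- apply(member_rts, 2L, stats::median, na.rm = TRUE)
    for (b in seq_len(nb)) {
      a <- greedy_assign(cons, rt_list[[b]], tol)
      members[b, ] <- ifelse(a > 0L, a, NA_integer_)
      member_rts[b, ] <- ifelse(a > 0L, rt_list[[b]][pmax(a, 1L)], NA_real_)
    }
  }

  complete <- colSums(!is.na(members)) == nb
  keep <- if (cfg$require_all_batches) complete else colSums(!is.na(members)) >= 1L
  members <- members[, keep, drop = FALSE]
  member_rts <- member_rts[, keep, drop = FALSE]
  k <- ncol(members)
  areas <- matrix(NA_real_, nb, k)
  for (b in seq_len(nb)) {
    hit <- !is.na(members[b, ])
    areas[b, hit] <- area_list[[b]][members[b, hit]]
  }
  # area screen: strictly greater than min_area in every (present) batch
  if (cfg$min_area > 0 && k > 0L) {
    ok <- apply(areas, 2L, function(col) all(col[!is.na(col)] > cfg$min_area))
    members <- members[, ok, drop = FALSE]
    member_rts <- member_rts[, ok, drop = FALSE]
    areas <- areas[, ok, drop = FALSE]
  }
  cons <- apply(member_rts, 2L, stats::median, na.rm = TRUE)
  ord <- order(cons)
  common_peak_matrix(panel$batch_ids, cons[ord],
                     areas[, ord, drop = FALSE],
                     rts = member_rts[, ord, drop = FALSE],
                     wavelength_nm = panel$wavelength_nm)
}

#' Locate a peak by relative retention value
#'
#' Returns the peak whose relative retention value (`rt / is_rt`) is
#' nearest the expected value, provided the relative deviation does not
#' exceed `tol`; ties are broken toward the larger area.
#'
#' @param table a [peak_table()].
#' @param is_rt internal-standard retention time (minutes, > 0).
#' @param expected_rrv expected relative retention value.
#' @param tol maximum relative deviation (fraction).
#' @return A one-row data frame (the located peak).
#' @export
locate_by_relative_retention <- function(table, is_rt, expected_rrv,
                                         tol = 0.05) {
  stopifnot(inherits(table, "peak_table"))
  assert_scalar_pos(is_rt, "is_rt")
  if (nrow(table) == 0L) stop_notfound("no peaks to search")
  dev <- abs(table$rt_min / is_rt - expected_rrv) / expected_rrv
  locate_pick(table, dev, tol,
              sprintf("no peak within %.3g of relative retention %.4g",
                      tol, expected_rrv))
}

#' Locate a peak by retention-time difference
#'
#' Mirror of [locate_by_relative_retention()] on the absolute difference
#' `(rt - is_rt) - expected_delta`, with `tol` in minutes.
#'
#' @inheritParams locate_by_relative_retention
#' @param expected_delta expected signed retention-time difference
#'   (minutes).
#' @param tol maximum absolute deviation (minutes).
#' @return A one-row data frame (the located peak).
#' @export
locate_by_rt_difference <- function(table, is_rt, expected_delta,
                                    tol = 0.5) {
  stopifnot(inherits(table, "peak_table"))
  assert_scalar_pos(is_rt, "is_rt")
  if (nrow(table) == 0L) stop_notfound("no peaks to search")
  dev <- abs((table$rt_min - is_rt) - expected_delta)
  locate_pick(table, dev, tol,
              sprintf("no peak within %.3g min of expected difference %.4g",
                      tol, expected_delta))
}

locate_pick <- function(table, dev, tol, msg) {
  ok <- which(dev <= tol)
  if (!length(ok)) {
    nearest <- which.min(dev)
    stop_notfound(msg, "; nearest candidate at rt ",
                  signif(table$rt_min[nearest], 6), " min (deviation ",
                  signif(dev[nearest], 4), ")")
  }
  best <- ok[dev[ok] == min(dev[ok])]
  if (length(best) > 1L) best <- best[which.max(table$area[best])]
  out <- as.data.frame(table)[best, , drop = FALSE]
  rownames(out) <- NULL
  out
}
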