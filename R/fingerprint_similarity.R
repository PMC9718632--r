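# Median-method reference fingerprint and batch-vs-reference similarity.

#' Build the reference fingerprint by the median method
#'
#' The reference fingerprint of a panel is the per-peak median of the
#' common-peak areas over batches (even batch count: the midpoint of the
#' two central order statistics), with the consensus retention times.
#'
#' @param matrix a [common_peak_matrix()] with at least one batch.
#' @return An object of class `fingerprint`: list with `peak_ids`,
#'   `reference_areas`, `reference_rts`.
#' @export
median_reference <- function(matrix) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  if (length(matrix$batch_ids) < 1L) stop_domain("need at least one batch")
  structure(list(peak_ids = matrix$peak_ids,
                 reference_areas = apply(matrix$areas, 2L, stats::median),
                 reference_rts = matrix$consensus_rt_min),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d common peaks, rt %.2f-%.2f min\n",
              length(x$peak_ids), min(x$reference_rts), max(x$reference_rts)))
  invisible(x)
}

#' Cosine (congruence) similarity of two area vectors
#'
#' The included-angle cosine `sum(a*b) / (||a|| * ||b||)`, the default
#' vector-similarity measure of chromatographic fingerprint software.
#' Lies in `[-1, 1]`; in `[0, 1]` for non-negative areas; scale-invariant.
#'
#' @param a,b numeric vectors of equal length, not both zero.
#' @return The similarity score.
#' @examples
#' cosine_similarity(c(1, 2, 3), c(3, 2, 1))  # 10/14
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b) || !length(a))
    stop_domain("vectors must have equal positive length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_domain("zero-norm vector")
  sum(a * b) / (na * nb)
}

#' Score every batch against a reference fingerprint
#'
#' @param matrix a [common_peak_matrix()].
#' @param fp a [fingerprint()] aligned with the matrix columns (defaults
#'   to the median reference of `matrix`).
#' @param metric `"cosine"` (default) or `"correlation"` (Pearson).
#' @return Named numeric vector of per-batch similarity scores.
#' @export
panel_similarities <- function(matrix, fp = median_reference(matrix),
                               metric = c("cosine", "correlation")) {
  stopifnot(inherits(matrix, "common_peak_matrix"), inherits(fp, "fingerprint"))
  metric <- match.arg(metric)
  if (!identical(length(fp$reference_areas), length(matrix$peak_ids)))
    stop_domain("fingerprint and matrix columns are not aligned")
  f <- if (metric == "cosine") {
    function(row) cosine_similarity(row, fp$reference_areas)
  } else {
    function(row) stats::cor(row, fp$reference_areas)
  }
  scores <- apply(matrix$areas, 1L, f)
  names(scores) <- matrix$batch_ids
  scores
}

#' Relative standard deviation (percent)
#'
#' `100 * sd / mean` with the sample (n - 1) denominator, the
#' pharmacopoeial convention for precision/repeatability reporting.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 2, 3))  # 50
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop_domain("rsd needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop_domain("rsd undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Express a peak table relative to a reference peak
#'
#' Divides every peak's retention time and area by those of the reference
#' peak; relative retention time and relative area are the statistics
#' validated in precision/stability/repeatability studies.
#'
#' @param table a [peak_table()].
#' @param ref_index row index of the reference peak, or an analyte label
#'   present in the table.
#' @return Data frame with `rel_rt`, `rel_area` (reference row = 1, 1).
#' @export
relative_to_reference_peak <- function(table, ref_index) {
  stopifnot(inherits(table, "peak_table"))
  if (is.character(ref_index)) {
    hit <- which(table$label == ref_index)
    if (!length(hit)) stop_notfound("reference peak not found: ", ref_index)
    ref_index <- hit[1L]
  }
  if (ref_index < 1L || ref_index > nrow(table))
    stop_notfound("reference peak index out of range: ", ref_index)
  data.frame(rel_rt = table$rt_min / table$rt_min[ref_index],
             rel_area = table$area / table$area[ref_index])
}

#' Per-peak retention-time and relative-area RSDs of a panel
#'
#' The validation statistics of a matched panel: per common peak, the RSD
#' of member retention times across batches and the RSD of the peak area
#' relative to a designated reference peak.
#'
#' @param matrix a [common_peak_matrix()] carrying member retention times.
#' @param ref_peak_id peak id (column) used as the relative-area
#'   reference.
#' @return Data frame with `peak_id`, `rt_rsd_pct`, `rel_area_rsd_pct`.
#' @export
validation_report <- function(matrix, ref_peak_id = 1L) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  if (is.null(matrix$rts))
    stop_domain("matrix carries no member retention times")
  if (!ref_peak_id %in% matrix$peak_ids)
    stop_notfound("reference peak id not in matrix: ", ref_peak_id)
  rel_area <- matrix$areas / matrix$areas[, ref_peak_id]
  data.frame(peak_id = matrix$peak_ids,
             rt_rsd_pct = apply(matrix$rts, 2L, rsd),
             rel_area_rsd_pct = apply(rel_area, 2L, function(v)
               if (stats::sd(v) == 0) 0 else rsd(v)))
}
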