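# Domain containers for chromatographic peak data.
#
# The pipeline's currency is the peak table: one sample, one detection
# wavelength, an rt-sorted list of (retention time, area) pairs. Batch
# panels collect the tables of repeated preparations of the same formula;
# cross-batch matching condenses a panel into a common-peak area matrix.

#' Construct a peak table
#'
#' A peak table holds the detected peaks of one chromatogram: one sample,
#' one detection wavelength, peaks sorted by retention time. Peaks closer
#' than 1e-6 min are treated as duplicates: the larger area is kept and a
#' warning is raised (never a silent drop).
#'
#' @param sample_id character scalar identifying the injection/batch.
#' @param wavelength_nm detection wavelength in nm (positive scalar).
#' @param rt_min numeric vector of retention times in minutes (>= 0).
#' @param area numeric vector of peak areas in arbitrary detector units
#'   (signal x min, >= 0).
#' @param height optional numeric vector of apex heights.
#' @param label optional character vector of analyte names ("unknown" where
#'   unidentified).
#' @return An object of class `peak_table`: a data frame with columns
#'   `rt_min`, `area`, `height`, `label` and attributes `sample_id`,
#'   `wavelength_nm`.
#' @examples
#' peak_table("B01", 237, rt_min = c(12.1, 33.5), area = c(4.2, 1.1))
#' @export
peak_table <- function(sample_id, wavelength_nm, rt_min, area,
                       height = NULL, label = NULL) {
  if (length(sample_id) != 1L || !nzchar(as.character(sample_id)))
    stop_domain("sample_id must be a non-empty scalar")
  assert_scalar_pos(wavelength_nm, "wavelength_nm")
  n <- length(rt_min)
  if (length(area) != n)
    stop_domain("rt_min and area must have equal length")
  bad_rt <- which(!is.finite(rt_min) | rt_min < 0)
  if (length(bad_rt))
    stop_domain("negative or non-finite rt_min at row(s) ",
                paste(bad_rt, collapse = ", "))
  bad_area <- which(!is.finite(area) | area < 0)
  if (length(bad_area))
    stop_domain("negative or non-finite area at row(s) ",
                paste(bad_area, collapse = ", "))
  height <- if (is.null(height)) rep(NA_real_, n) else as.numeric(height)
  label <- if (is.null(label)) rep("unknown", n) else as.character(label)
  if (length(height) != n || length(label) != n)
    stop_domain("height/label must match the number of peaks")

  ord <- order(rt_min)
  df <- data.frame(rt_min = as.numeric(rt_min)[ord], area = as.numeric(area)[ord],
                   height = height[ord], label = label[ord],
                   stringsAsFactors = FALSE)
  # dedup: peaks within 1e-6 min are one peak; keep the larger area
  if (n > 1L) {
    dup <- which(diff(df$rt_min) < 1e-6)
    if (length(dup)) {
      warning("duplicate retention times collapsed (larger area kept): rt = ",
              paste(signif(df$rt_min[dup], 8), collapse = ", "))
      drop <- integer(0)
      for (i in dup) {
        drop <- c(drop, if (df$area[i] >= df$area[i + 1L]) i + 1L else i)
      }
      df <- df[-unique(drop), , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  structure(df,
            sample_id = as.character(sample_id),
            wavelength_nm = as.numeric(wavelength_nm),
            class = c("peak_table", "data.frame"))
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> sample '%s' at %g nm: %d peaks\n",
              attr(x, "sample_id"), attr(x, "wavelength_nm"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more peaks\n")
  invisible(x)
}

#' Construct a raw chromatogram trace
#'
#' @param time_min strictly increasing time grid in minutes.
#' @param signal detector response at each grid point.
#' @param wavelength_nm detection wavelength in nm.
#' @return An object of class `trace` (list with `time_min`, `signal`,
#'   `wavelength_nm`).
#' @export
chrom_trace <- function(time_min, signal, wavelength_nm) {
  if (length(time_min) != length(signal))
    stop_domain("time_min and signal must have equal length")
  if (length(time_min) > 1L && any(diff(time_min) <= 0))
    stop_domain("time_min must be strictly increasing")
  assert_scalar_pos(wavelength_nm, "wavelength_nm")
  structure(list(time_min = as.numeric(time_min), signal = as.numeric(signal),
                 wavelength_nm = as.numeric(wavelength_nm)),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d points, %.2f-%.2f min, %g nm\n",
              length(x$time_min), min(x$time_min), max(x$time_min),
              x$wavelength_nm))
  invisible(x)
}

#' Bundle peak tables of repeated batches into a panel
#'
#' @param tables list of [peak_table()] objects sharing one wavelength, with
#'   unique sample ids; at least two batches.
#' @param metadata optional named list carried along (acquisition dates etc.).
#' @return An object of class `batch_panel`.
#' @export
batch_panel <- function(tables, metadata = list()) {
  if (!is.list(tables) || length(tables) < 2L)
    stop_domain("a batch panel needs at least 2 peak tables")
  if (!all(vapply(tables, inherits, logical(1), "peak_table")))
    stop_domain("all panel elements must be peak_table objects")
  wl <- vapply(tables, attr, numeric(1), "wavelength_nm")
  if (length(unique(wl)) != 1L)
    stop_domain("all panel tables must share one wavelength")
  ids <- vapply(tables, attr, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop_domain("duplicate sample_id in panel: ", ids[duplicated(ids)][1L])
  structure(list(tables = tables, batch_ids = ids, wavelength_nm = wl[1L],
                 metadata = metadata),
            class = "batch_panel")
}

#' @export
print.batch_panel <- function(x, ...) {
  cat(sprintf("<batch_panel> %d batches at %g nm: %s\n",
              length(x$tables), x$wavelength_nm,
              paste(x$batch_ids, collapse = ", ")))
  invisible(x)
}

#' Construct a common-peak matrix
#'
#' Batches x matched-common-peaks area matrix. A column exists only if the
#' peak matched in every batch of the panel; columns are ordered by
#' consensus retention time and numbered 1..K in elution order.
#'
#' @param batch_ids character vector of batch identifiers (rows).
#' @param consensus_rt_min numeric vector of per-peak consensus retention
#'   times (columns), strictly increasing.
#' @param areas numeric matrix, batches x peaks.
#' @param rts optional numeric matrix of per-batch member retention times
#'   (same shape as `areas`).
#' @param wavelength_nm detection wavelength.
#' @return An object of class `common_peak_matrix`.
#' @export
common_peak_matrix <- function(batch_ids, consensus_rt_min, areas, rts = NULL,
                               wavelength_nm = NA_real_) {
  areas <- as.matrix(areas)
  if (nrow(areas) != length(batch_ids))
    stop_domain("areas must have one row per batch")
  if (ncol(areas) != length(consensus_rt_min))
    stop_domain("areas must have one column per consensus rt")
  if (length(consensus_rt_min) > 1L && any(diff(consensus_rt_min) <= 0))
    stop_domain("consensus_rt_min must be strictly increasing")
  if (any(!is.finite(areas)) || any(areas < 0))
    stop_domain("areas must be finite and non-negative")
  peak_ids <- seq_along(consensus_rt_min)
  dimnames(areas) <- list(batch_ids, paste0("peak_", peak_ids))
  if (!is.null(rts)) {
    rts <- as.matrix(rts)
    if (!identical(dim(rts), dim(areas)))
      stop_domain("rts must have the same shape as areas")
    dimnames(rts) <- dimnames(areas)
  }
  structure(list(batch_ids = as.character(batch_ids),
                 peak_ids = peak_ids,
                 consensus_rt_min = as.numeric(consensus_rt_min),
                 areas = areas, rts = rts,
                 wavelength_nm = wavelength_nm),
            class = "common_peak_matrix")
}

#' @export
print.common_peak_matrix <- function(x, ...) {
  cat(sprintf("<common_peak_matrix> %d batches x %d common peaks\n",
              length(x$batch_ids), length(x$peak_ids)))
  invisible(x)
}

# ---- CSV interchange ----------------------------------------------------

required_peak_cols <- c("sample_id", "wavelength_nm", "rt_min", "area")

#' Read a peak table from CSV
#'
#' Expected columns: `sample_id`, `wavelength_nm`, `rt_min`, `area`, plus
#' optional `height` and `label`. Unknown columns are preserved as a
#' metadata attribute. Invalid rows (negative rt/area) raise a validation
#' error naming the offending row, never a silent drop.
#'
#' @param path path to a UTF-8, comma-separated file with a header row.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_peak_cols, names(df))
  if (length(missing_cols))
    stop_format("missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    stop_format("empty peak table: ", path)
  if (length(unique(df$sample_id)) != 1L)
    stop_format("a peak-table CSV must contain a single sample_id")
  if (length(unique(df$wavelength_nm)) != 1L)
    stop_format("a peak-table CSV must contain a single wavelength")
  extra <- setdiff(names(df), c(required_peak_cols, "height", "label"))
  tab <- peak_table(df$sample_id[1L], df$wavelength_nm[1L],
                    rt_min = df$rt_min, area = df$area,
                    height = if ("height" %in% names(df)) df$height,
                    label = if ("label" %in% names(df)) df$label)
  if (length(extra)) attr(tab, "metadata") <- df[extra]
  tab
}

#' Write a peak table to CSV
#'
#' Fixed column order `sample_id, wavelength_nm, rt_min, area, height,
#' label`; numbers serialized with 10 significant digits so that
#' `read_peak_table(write_peak_table(x))` round-trips.
#'
#' @param table a [peak_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(sample_id = attr(table, "sample_id"),
                   wavelength_nm = attr(table, "wavelength_nm"),
                   rt_min = format(table$rt_min, digits = 10, trim = TRUE,
                                   scientific = FALSE),
                   area = format(table$area, digits = 10, trim = TRUE,
                                 scientific = FALSE),
                   height = table$height, label = table$label,
                   stringsAsFactors = FALSE)
  if (nrow(table) == 0L) df <- df[0L, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw chromatogram trace from CSV
#'
#' Expected columns: `time_min`, `signal`, `wavelength_nm`.
#'
#' @param path input path.
#' @return A [chrom_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "signal", "wavelength_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_format("missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  chrom_trace(df$time_min, df$signal, df$wavelength_nm[1L])
}

#' Write a raw chromatogram trace to CSV
#'
#' @param trace a [chrom_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace"))
  utils::write.csv(data.frame(time_min = trace$time_min, signal = trace$signal,
                              wavelength_nm = trace$wavelength_nm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a common-peak matrix to CSV
#'
#' Two files: `<stem>_areas.csv` (rows = batches, columns = peak_1..peak_K)
#' and `<stem>_consensus_rt.csv`.
#'
#' @param mat a [common_peak_matrix()].
#' @param stem path stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_common_peak_matrix <- function(mat, stem) {
  stopifnot(inherits(mat, "common_peak_matrix"))
  p1 <- paste0(stem, "_areas.csv")
  p2 <- paste0(stem, "_consensus_rt.csv")
  utils::write.csv(data.frame(batch_id = mat$batch_ids, mat$areas,
                              check.names = FALSE),
                   p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(peak_id = mat$peak_ids,
                              consensus_rt_min = mat$consensus_rt_min),
                   p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
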