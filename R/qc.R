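# Sample-level quality control applied before clustering: samples must carry
# complete metadata (cell type and donor ID) and a plausible number of called
# peaks. Both cutoffs are strict inequalities; a sample sitting exactly on a
# boundary is retained.

#' Remove samples with incomplete metadata
#'
#' Samples without a cell type or donor ID cannot enter the replication test
#' and are removed up front.
#'
#' @param samples metadata `data.table` (see [read_metadata()]).
#' @return list with `passed` (metadata subset) and `removed`
#'   (`data.table` of `sample_id`, `reason`).
#' @export
filter_by_metadata <- function(samples) {
  samples <- data.table::as.data.table(samples)
  bad <- samples$cell_type == "" | samples$donor_id == ""
  removed <- data.table::data.table(
    sample_id = samples$sample_id[bad],
    reason = ifelse(samples$cell_type[bad] == "",
                    "missing cell_type", "missing donor_id"))
  list(passed = samples[!bad], removed = removed)
}

#' Remove samples with an outlying number of peaks
#'
#' Samples with fewer than `min_peaks` or more than `max_peaks` autosomal
#' peaks are treated as outliers (failed or saturated experiments). The
#' comparisons are strict, so counts equal to a threshold are retained.
#'
#' @param samples metadata `data.table`.
#' @param peak_counts named integer vector of per-sample peak counts, names
#'   matching `sample_id`. Counts are taken on the autosome-filtered peak set.
#' @param min_peaks,max_peaks retention window; defaults 40000 and 500000.
#' @return list with `passed` and `removed` as in [filter_by_metadata()].
#' @export
filter_by_peak_count <- function(samples, peak_counts,
                                 min_peaks = 40000, max_peaks = 500000) {
  abort_if(min_peaks < 0 || max_peaks < 0 || min_peaks > max_peaks,
           "invalid peak-count thresholds")
  samples <- data.table::as.data.table(samples)
  n <- peak_counts[samples$sample_id]
  n[is.na(n)] <- 0L
  bad <- n < min_peaks | n > max_peaks
  removed <- data.table::data.table(
    sample_id = samples$sample_id[bad],
    reason = ifelse(n[bad] < min_peaks,
                    sprintf("too few peaks (%d < %d)", n[bad], as.integer(min_peaks)),
                    sprintf("too many peaks (%d > %d)", n[bad], as.integer(max_peaks))))
  list(passed = samples[!bad], removed = removed)
}

#' Run both sample-level quality filters and build a QC report
#'
#' @inheritParams filter_by_peak_count
#' @return list of class `qc_report`: `passed` metadata, `removed` table,
#'   and counts `n_input`, `n_removed_metadata`, `n_removed_peakcount`,
#'   `n_passed` (which always reconcile with the input size).
#' @export
qc_samples <- function(samples, peak_counts,
                       min_peaks = 40000, max_peaks = 500000) {
  m <- filter_by_metadata(samples)
  p <- filter_by_peak_count(m$passed, peak_counts, min_peaks, max_peaks)
  rep <- structure(list(
    passed = p$passed,
    removed = data.table::rbindlist(list(m$removed, p$removed)),
    n_input = nrow(samples),
    n_removed_metadata = nrow(m$removed),
    n_removed_peakcount = nrow(p$removed),
    n_passed = nrow(p$passed)), class = "qc_report")
  stopifnot(rep$n_passed ==
              rep$n_input - rep$n_removed_metadata - rep$n_removed_peakcount)
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_input, " samples in; removed ",
      x$n_removed_metadata, " (metadata) + ", x$n_removed_peakcount,
      " (peak count); ", x$n_passed, " passed\n", sep = "")
  invisible(x)
}

#' Write a QC report's removal table as TSV
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  data.table::fwrite(report$removed, path, sep = "\t")
  invisible(path)
}
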