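# Readers and writers for the standard formats the pipeline touches:
# BED narrowPeak input, sample metadata tables, and BED6 / GFF3 / TSV matrix
# exports. Internal coordinates are BED-style 0-based half-open throughout;
# GFF3 export converts to 1-based inclusive.

#' Read a narrowPeak (or plain BED) file of peak calls
#'
#' Parses one sample's peak calls into a `data.table` of peaks. Coordinates
#' are kept 0-based half-open as in BED. The accessibility significance of a
#' peak, `neglog10_p`, is taken from narrowPeak column 8 (-log10 p-value);
#' where that column is `-1` (peak callers use it as a sentinel for "not
#' computed") or absent, the signalValue in column 7 is used instead, and 0
#' when neither is present.
#'
#' @param path path to a tab-separated narrowPeak (10 columns) or BED
#'   (>= 3 columns) file. May be empty.
#' @param sample_id sample identifier attached to every peak.
#' @param autosomes_only drop peaks on non-autosomal chromosomes (default
#'   TRUE; the atlas is restricted to chr1..chr22).
#' @return `data.table` with columns `chrom`, `start`, `end`, `signal`,
#'   `neglog10_p`, `sample_id`; zero rows for an empty file.
#' @export
read_narrowpeak <- function(path, sample_id, autosomes_only = TRUE) {
  abort_if(!file.exists(path), "cannot read peak file: ", path)
  dt <- if (file.size(path) == 0L) data.table::data.table() else
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), signal = numeric(),
                                  neglog10_p = numeric(),
                                  sample_id = character()))
  }
  abort_if(ncol(dt) < 3L, "peak file ", path, ": fewer than 3 columns")
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end |
                 start < 0 | start != floor(start) | end != floor(end))
  abort_if(length(bad) > 0L,
           "peak file ", path, ": malformed coordinates at line ", bad[1])
  signal <- if (ncol(dt) >= 7L) suppressWarnings(as.numeric(dt[[7]])) else
    rep(NA_real_, nrow(dt))
  pval <- if (ncol(dt) >= 8L) suppressWarnings(as.numeric(dt[[8]])) else
    rep(NA_real_, nrow(dt))
  signal[!is.finite(signal)] <- 0
  neglog10_p <- ifelse(is.finite(pval) & pval >= 0, pval, signal)
  neglog10_p[neglog10_p < 0] <- 0
  out <- data.table::data.table(
    chrom = normalize_chrom(dt[[1]]),
    start = as.integer(start), end = as.integer(end),
    signal = pmax(signal, 0), neglog10_p = neglog10_p,
    sample_id = as.character(sample_id))
  if (autosomes_only) out <- out[is_autosome(out$chrom)]
  data.table::setorder(out, chrom, start, end)
  out[]
}

#' Read a sample metadata table
#'
#' The metadata table is tab-separated with a header and must carry the
#' columns `sample_id`, `cell_type`, `donor_id`, `project` and `path`.
#' Missing cell types / donor IDs are kept as empty strings here; they are
#' removed later by [filter_by_metadata()], not rejected at read time.
#'
#' @param path path to the metadata TSV.
#' @return `data.table`, one row per sample.
#' @export
read_metadata <- function(path) {
  abort_if(!file.exists(path), "cannot read metadata: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = NULL)
  required <- c("sample_id", "cell_type", "donor_id", "project", "path")
  missing <- setdiff(required, names(dt))
  abort_if(length(missing) > 0L,
           "metadata missing required column(s): ",
           paste(missing, collapse = ", "))
  for (col in required) data.table::set(dt, j = col,
                                        value = ifelse(is.na(dt[[col]]), "", dt[[col]]))
  dup <- dt$sample_id[duplicated(dt$sample_id)]
  abort_if(length(dup) > 0L, "duplicate sample_id in metadata: ", dup[1])
  dt[]
}

#' Read all peak files listed in a metadata table
#'
#' @param metadata a metadata `data.table` from [read_metadata()]; relative
#'   `path` entries are resolved against `base_dir`.
#' @param base_dir directory that relative peak paths are resolved against.
#' @param autosomes_only passed to [read_narrowpeak()].
#' @return one `data.table` of peaks for all samples.
#' @export
read_all_peaks <- function(metadata, base_dir = ".", autosomes_only = TRUE) {
  lst <- lapply(seq_len(nrow(metadata)), function(i) {
    p <- metadata$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, metadata$path[i])
    read_narrowpeak(p, metadata$sample_id[i], autosomes_only = autosomes_only)
  })
  data.table::rbindlist(lst)
}

#' Export the per-cell-type accessibility matrix as one GFF3 file per cell type
#'
#' Writes `<cell_type>.gff3` for every cell type, containing one
#' `open_chromatin_region` feature per site with non-zero intensity in that
#' cell type (inaccessible sites are omitted so genome-browser tracks show
#' only accessible regions). Internal 0-based half-open coordinates are
#' converted to the 1-based inclusive GFF3 convention (`start + 1`, `end`).
#'
#' @param ct_matrix a `cell_type_matrix` from [collapse_by_celltype()] /
#'   [filter_active()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
export_gff3 <- function(ct_matrix, out_dir) {
  stopifnot(inherits(ct_matrix, "cell_type_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(out_dir), "cannot create output directory: ", out_dir)
  spans <- data.table::as.data.table(ct_matrix$spans)
  vals <- ct_matrix$values
  ord <- order(spans$chrom, spans$start, spans$end)
  spans <- spans[ord]
  vals <- vals[ord, , drop = FALSE]
  paths <- character(0)
  for (ct in colnames(vals)) {
    fn <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", ct), ".gff3"))
    keep <- vals[, ct] > 0
    lines <- "##gff-version 3"
    if (any(keep)) {
      s <- spans[keep]
      v <- vals[keep, ct]
      lines <- c(lines, paste(
        s$chrom, "dhsatlas", "open_chromatin_region",
        s$start + 1L, s$end, format(v, digits = 8, trim = TRUE, scientific = FALSE),
        ".", ".",
        paste0("ID=", s$cluster_id, ";intensity=",
               format(v, digits = 8, trim = TRUE, scientific = FALSE)),
        sep = "\t"))
    }
    writeLines(lines, fn)
    paths <- c(paths, fn)
  }
  invisible(paths)
}

#' Export the final site-by-cell-type matrix as a sorted TSV
#'
#' One row per replicable site (`chrom`, `start`, `end`, `cluster_id`, then
#' one column per cell type), sorted by chromosome then start so the file is
#' ready for bgzip/tabix indexing.
#'
#' @param ct_matrix a `cell_type_matrix`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_matrix <- function(ct_matrix, path) {
  stopifnot(inherits(ct_matrix, "cell_type_matrix"))
  spans <- data.table::as.data.table(ct_matrix$spans)
  out <- cbind(spans[, c("chrom", "start", "end", "cluster_id")],
               data.table::as.data.table(ct_matrix$values))
  data.table::setorder(out, chrom, start, end)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Re-read a matrix TSV written by [export_matrix()]
#'
#' @param path TSV file path.
#' @return a `cell_type_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  fixed <- c("chrom", "start", "end", "cluster_id")
  abort_if(!all(fixed %in% names(dt)), "not a matrix TSV: ", path)
  vals <- as.matrix(dt[, setdiff(names(dt), fixed), with = FALSE])
  rownames(vals) <- dt$cluster_id
  new_cell_type_matrix(vals, dt[, fixed, with = FALSE])
}

#' Export cluster spans as BED6
#'
#' @param clusters a `dhs_clusters` object or a `data.table` with
#'   `chrom`, `start`, `end`, `cluster_id`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_bed <- function(clusters, path) {
  spans <- if (inherits(clusters, "dhs_clusters")) clusters$clusters else
    data.table::as.data.table(clusters)
  out <- data.table::data.table(
    chrom = spans$chrom, start = spans$start, end = spans$end,
    name = as.character(spans$cluster_id), score = 0L, strand = ".")
  data.table::setorder(out, chrom, start, end)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

new_cell_type_matrix <- function(values, spans) {
  structure(list(values = values, spans = data.table::as.data.table(spans)),
            class = "cell_type_matrix")
}

#' @export
print.cell_type_matrix <- function(x, ...) {
  cat("<cell_type_matrix> ", nrow(x$values), " sites x ",
      ncol(x$values), " cell types\n", sep = "")
  invisible(x)
}
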