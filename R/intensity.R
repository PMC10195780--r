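# Accessibility intensities of replicable clusters. Each cluster receives,
# per sample, the -log10(p) of its most significant member peak from that
# sample (0 when the sample has no member peak: inaccessible). Intensities
# are then made comparable across samples and generating centers by
# per-sample scaling to [0, 1] followed by subsampled quantile normalization,
# collapsed to cell types by the median, and filtered on a minimum activity.

#' Raw intensity matrix of replicable clusters
#'
#' Entry (c, s) is the maximum `neglog10_p` over the member peaks of cluster
#' c coming from sample s, and 0 when the sample contributes no member peak.
#'
#' @param clusters a `dhs_clusters` object.
#' @param sample_ids column order of the matrix (all QC-passed samples).
#' @param cluster_ids rows to keep, typically the replicable set from
#'   [filter_replicable()]; default all clusters.
#' @return numeric matrix (clusters x samples) with dimnames.
#' @export
assign_intensities <- function(clusters, sample_ids,
                               cluster_ids = clusters$clusters$cluster_id) {
  stopifnot(inherits(clusters, "dhs_clusters"))
  mem <- clusters$members[clusters$members$cluster_id %in% cluster_ids]
  agg <- mem[, list(v = max(neglog10_p)), by = c("cluster_id", "sample_id")]
  M <- matrix(0, length(cluster_ids), length(sample_ids),
              dimnames = list(as.character(sort(cluster_ids)), sample_ids))
  agg <- agg[agg$sample_id %in% sample_ids]
  M[cbind(match(as.character(agg$cluster_id), rownames(M)),
          match(agg$sample_id, colnames(M)))] <- agg$v
  M
}

#' Scale each sample's intensities into \[0, 1\]
#'
#' Each column is divided by its maximum, so the strongest site in every
#' sample gets intensity 1 while zeros keep meaning "inaccessible". An
#' all-zero column is left unchanged with a warning.
#'
#' @param mat raw intensity matrix (non-negative).
#' @return matrix with every column in \[0, 1\].
#' @export
scale_per_sample <- function(mat) {
  abort_if(any(mat < 0), "intensities must be non-negative")
  mx <- apply(mat, 2L, max)
  if (any(mx == 0)) {
    warning("all-zero sample column(s): ",
            paste(colnames(mat)[mx == 0], collapse = ", "))
    mx[mx == 0] <- 1
  }
  sweep(mat, 2L, mx, "/")
}

#' Subsampled quantile normalization across samples
#'
#' From each sample (column), `min(n_subsample, #nonzero)` non-zero entries
#' are drawn without replacement; the sorted subsamples define a common
#' reference distribution (rank-wise mean across samples), each sampled value
#' is replaced by the reference value at its rank, and the remaining non-zero
#' values are mapped by monotone piecewise-linear interpolation through the
#' sampled (original -> normalized) pairs, clipped at the extremes. Zeros are
#' untouched: absence stays absence.
#'
#' @param mat per-sample scaled intensity matrix.
#' @param n_subsample number of non-zero sites sampled per column
#'   (default 10000).
#' @param seed seed for the subsampling draws.
#' @return normalized matrix of the same shape; with fewer than 2 columns
#'   the input is returned unchanged with a warning.
#' @export
quantile_normalize <- function(mat, n_subsample = 10000L, seed = 1L) {
  abort_if(any(mat < 0), "intensities must be non-negative")
  if (ncol(mat) < 2L) {
    warning("fewer than 2 samples; quantile normalization skipped")
    return(mat)
  }
  nz_idx <- lapply(seq_len(ncol(mat)), function(j) which(mat[, j] > 0))
  usable <- vapply(nz_idx, length, 1L) > 0L
  if (!all(usable))
    warning("column(s) with no non-zero entries are left unchanged")
  cols <- which(usable)
  k <- pmin(n_subsample, vapply(nz_idx, length, 1L))
  sampled <- vector("list", ncol(mat))
  with_seed(derive_seed(seed, 104729L), {
    for (j in cols) {
      idx <- nz_idx[[j]]
      sampled[[j]] <- if (length(idx) <= k[j]) idx else sample(idx, k[j])
    }
  })
  # reference distribution: rank-wise mean of the sorted subsamples,
  # aligned on a common quantile grid when subsample sizes differ
  grid_n <- max(k[cols])
  probs <- if (grid_n == 1L) 0.5 else seq(0, 1, length.out = grid_n)
  on_grid <- vapply(cols, function(j) {
    v <- sort(mat[sampled[[j]], j])
    if (length(v) == grid_n) v
    else stats::approx(seq(0, 1, length.out = length(v)), v, xout = probs,
                       rule = 2, ties = "ordered")$y
  }, numeric(grid_n))
  ref <- rowMeans(matrix(on_grid, nrow = grid_n))
  out <- mat
  for (j in cols) {
    v <- mat[sampled[[j]], j]
    ord <- order(v)
    kk <- length(v)
    ref_j <- if (kk == grid_n) ref
    else stats::approx(probs, ref, xout = seq(0, 1, length.out = kk),
                       rule = 2, ties = "ordered")$y
    norm_v <- numeric(kk)
    norm_v[ord] <- ref_j
    out[sampled[[j]], j] <- norm_v
    # interpolate the non-sampled non-zero values through the sampled pairs
    rest <- setdiff(nz_idx[[j]], sampled[[j]])
    if (length(rest) > 0L) {
      if (length(unique(v)) < 2L) {
        out[rest, j] <- ref_j[1L]
      } else {
        map <- stats::approx(v[ord], ref_j, xout = mat[rest, j],
                             rule = 2, ties = mean)
        out[rest, j] <- pmin(pmax(map$y, 0), 1)
      }
    }
  }
  out
}

#' Collapse sample intensities to cell types by the median
#'
#' Entry (c, t) is the median normalized intensity over all samples of cell
#' type t, zeros (samples lacking the site) included; for an even number of
#' samples the mean of the two middle values is used (the `stats::median()`
#' convention).
#'
#' @param mat normalized intensity matrix (clusters x samples).
#' @param samples metadata `data.table` mapping `sample_id` to `cell_type`.
#' @param spans `data.table` of cluster spans (`cluster_id`, `chrom`,
#'   `start`, `end`) for the matrix rows, carried into the result.
#' @return a `cell_type_matrix`.
#' @export
collapse_by_celltype <- function(mat, samples, spans) {
  samples <- data.table::as.data.table(samples)
  cts <- sort(unique(samples$cell_type[samples$cell_type != ""]))
  abort_if(length(cts) == 0L, "no cell types in metadata")
  vals <- vapply(cts, function(ct) {
    ids <- samples$sample_id[samples$cell_type == ct]
    ids <- intersect(ids, colnames(mat))
    abort_if(length(ids) == 0L, "cell type with no sample columns: ", ct)
    apply(mat[, ids, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(mat)))
  vals <- matrix(vals, nrow = nrow(mat),
                 dimnames = list(rownames(mat), cts))
  spans <- data.table::as.data.table(spans)
  spans <- spans[match(rownames(mat), as.character(spans$cluster_id))]
  new_cell_type_matrix(vals, spans)
}

#' Mean between-batch distance of same-cell-type sample profiles
#'
#' Average Euclidean distance between the intensity profiles of sample pairs
#' that share a cell type but come from different generating centers. A drop
#' in this quantity after normalization indicates batch-effect removal.
#'
#' @param mat intensity matrix (clusters x samples).
#' @param samples metadata with `sample_id`, `cell_type`, `project`.
#' @return mean distance (NA if no same-cell-type cross-batch pair exists).
#' @export
batch_distance <- function(mat, samples) {
  samples <- data.table::as.data.table(samples)
  samples <- samples[samples$sample_id %in% colnames(mat)]
  d <- c()
  for (ct in unique(samples$cell_type)) {
    ids <- samples[samples$cell_type == ct]
    if (nrow(ids) < 2L) next
    for (i in seq_len(nrow(ids) - 1L)) for (j in seq(i + 1L, nrow(ids))) {
      if (ids$project[i] != ids$project[j])
        d <- c(d, sqrt(sum((mat[, ids$sample_id[i]] -
                              mat[, ids$sample_id[j]])^2)))
    }
  }
  if (length(d) == 0L) NA_real_ else mean(d)
}

#' Drop sites that are not clearly active anywhere
#'
#' Keeps sites whose maximum median intensity over cell types is strictly
#' greater than `threshold` (default 0.25).
#'
#' @param ct_matrix a `cell_type_matrix`.
#' @param threshold activity threshold in \[0, 1).
#' @return the filtered `cell_type_matrix`.
#' @export
filter_active <- function(ct_matrix, threshold = 0.25) {
  stopifnot(inherits(ct_matrix, "cell_type_matrix"))
  abort_if(threshold < 0 || threshold >= 1, "threshold must be in [0, 1)")
  keep <- apply(ct_matrix$values, 1L, max) > threshold
  new_cell_type_matrix(ct_matrix$values[keep, , drop = FALSE],
                       ct_matrix$spans[keep])
}
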