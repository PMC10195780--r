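# Replication-based quality check of DHS clusters. For each of K randomized
# runs, two replicate samples are drawn per cell type (cell types with fewer
# than two replicates are excluded) and a 2x2 presence/absence contingency
# table is pooled over cell types: does the cluster appear in the first
# replicate, in the second, in both, in neither? Concordant presence across
# replicates is evidence the cluster is a real regulatory site rather than a
# peak-calling artifact. Each run's Pearson chi-squared statistic follows a
# chi-squared(1) null; the K-run sum is referred to chi-squared(K), and
# clusters with p <= alpha are kept as replicable.

#' Draw randomized replicate pairings
#'
#' For each of `n_runs` runs, draws one unordered pair of replicate samples
#' per cell type, uniformly over all pairs, for every cell type with at least
#' two replicate samples. Cell types with exactly two replicates necessarily
#' contribute the same pair in every run; cell types with a single replicate
#' are excluded. Run `k` is seeded with `seed XOR k`, so pairings are
#' reproducible run by run.
#'
#' @param samples metadata `data.table` with `sample_id` and `cell_type`.
#' @param n_runs number of runs (default 10).
#' @param seed master seed.
#' @return list of length `n_runs`; each element a `data.table` with columns
#'   `cell_type`, `s1`, `s2`.
#' @export
draw_pairings <- function(samples, n_runs = 10L, seed = 1L) {
  samples <- data.table::as.data.table(samples)
  samples <- samples[samples$cell_type != ""]
  reps <- lapply(split(samples$sample_id, samples$cell_type),
                 function(x) sort(unique(x)))
  reps <- reps[vapply(reps, length, 1L) >= 2L]
  abort_if(length(reps) == 0L,
           "no cell type has at least two replicate samples")
  cts <- sort(names(reps))
  lapply(seq_len(n_runs), function(k) {
    with_seed(derive_seed(seed, k), {
      pairs <- lapply(cts, function(ct) {
        ids <- reps[[ct]]
        pick <- sample.int(length(ids), 2L)
        data.table::data.table(cell_type = ct,
                               s1 = ids[pick[1L]], s2 = ids[pick[2L]])
      })
      data.table::rbindlist(pairs)
    })
  })
}

#' Presence/absence contingency table of one cluster under one pairing
#'
#' For each paired cell type, sets the indicator x to 1 if any member peak of
#' the cluster comes from the first sample of the pair, and y likewise for
#' the second; counts are pooled over cell types.
#'
#' @param member_samples character vector of sample IDs contributing at least
#'   one member peak to the cluster.
#' @param pairing one element of [draw_pairings()].
#' @return named integer vector `n11`, `n10`, `n01`, `n00`.
#' @export
presence_table <- function(member_samples, pairing) {
  x <- pairing$s1 %in% member_samples
  y <- pairing$s2 %in% member_samples
  c(n11 = sum(x & y), n10 = sum(x & !y), n01 = sum(!x & y),
    n00 = sum(!x & !y))
}

#' Single-run replication statistic
#'
#' Pearson chi-squared statistic (no continuity correction) of the pooled
#' 2x2 presence table,
#' `T (n11 n00 - n10 n01)^2 / ((n11+n10)(n01+n00)(n11+n01)(n10+n00))`,
#' which follows chi-squared(1) under the null of no replicate concordance.
#' Degenerate tables are scored by convention: a cluster present in both
#' replicates of every paired cell type (`n11 == T`) receives the Pearson
#' maximum `T`, so constitutively open sites pass; a cluster absent
#' everywhere (`n00 == T`) receives 0; any other constant margin (association
#' unidentifiable) receives 0. Vectorized over table entries.
#'
#' @param n11,n10,n01,n00 table counts (presence in first/second replicate).
#' @return numeric statistic(s) `>= 0`.
#' @examples
#' single_run_statistic(50, 0, 0, 50)  # 100
#' single_run_statistic(25, 25, 25, 25)  # 0
#' @export
single_run_statistic <- function(n11, n10, n01, n00) {
  abort_if(any(n11 < 0 | n10 < 0 | n01 < 0 | n00 < 0),
           "contingency counts must be non-negative")
  T <- n11 + n10 + n01 + n00
  abort_if(any(T < 1), "empty contingency table")
  r1 <- n11 + n10; r0 <- n01 + n00
  c1 <- n11 + n01; c0 <- n10 + n00
  s <- numeric(length(T))
  ok <- r1 > 0 & r1 < T & c1 > 0 & c1 < T
  s[ok] <- T[ok] * (n11[ok] * n00[ok] - n10[ok] * n01[ok])^2 /
    (r1[ok] * r0[ok] * c1[ok] * c0[ok])
  s[n11 == T] <- T[n11 == T]
  s
}

#' Combine per-run statistics into the chi-squared(K) replication test
#'
#' @param run_stats numeric vector (one cluster) or matrix (clusters x runs)
#'   of per-run statistics.
#' @param alpha significance threshold; a cluster is replicable iff its
#'   combined p-value is `<= alpha` (inclusive).
#' @return `data.table` with `S` (summed statistic), `df` (number of runs),
#'   `p_value` (upper tail of chi-squared(df) at S) and `replicable`.
#' @export
combined_test <- function(run_stats, alpha = 0.05) {
  if (is.vector(run_stats)) run_stats <- matrix(run_stats, nrow = 1L)
  K <- ncol(run_stats)
  abort_if(K < 1L, "need at least one run")
  abort_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  S <- rowSums(run_stats)
  p <- stats::pchisq(S, df = K, lower.tail = FALSE)
  data.table::data.table(S = S, df = K, p_value = p, replicable = p <= alpha)
}

# clusters x samples logical presence matrix from a dhs_clusters object
presence_matrix <- function(clusters, sample_ids) {
  stopifnot(inherits(clusters, "dhs_clusters"))
  m <- unique(clusters$members[, c("cluster_id", "sample_id")])
  n_cl <- nrow(clusters$clusters)
  P <- matrix(FALSE, n_cl, length(sample_ids),
              dimnames = list(as.character(clusters$clusters$cluster_id),
                              sample_ids))
  P[cbind(match(m$cluster_id, clusters$clusters$cluster_id),
          match(m$sample_id, sample_ids))] <- TRUE
  P
}

# per-run statistics for every cluster given a presence matrix and pairings
run_statistics <- function(P, pairings) {
  n_cl <- nrow(P)
  stats <- matrix(0, n_cl, length(pairings))
  for (k in seq_along(pairings)) {
    pr <- pairings[[k]]
    n11 <- n10 <- n01 <- n00 <- numeric(n_cl)
    for (i in seq_len(nrow(pr))) {
      x <- P[, pr$s1[i]]
      y <- P[, pr$s2[i]]
      n11 <- n11 + (x & y); n10 <- n10 + (x & !y)
      n01 <- n01 + (!x & y); n00 <- n00 + (!x & !y)
    }
    stats[, k] <- single_run_statistic(n11, n10, n01, n00)
  }
  stats
}

#' Replication test of every DHS cluster
#'
#' Draws `n_runs` randomized replicate pairings, computes the per-run
#' chi-squared(1) statistics for every cluster, and combines them into the
#' chi-squared(`n_runs`) test.
#'
#' @param clusters a `dhs_clusters` object.
#' @param samples metadata `data.table` of QC-passed samples.
#' @param n_runs number of randomized pairing runs (default 10).
#' @param alpha significance threshold (default 0.05, inclusive).
#' @param seed master seed for the pairing draws.
#' @return object of class `replication_result`: `results` (`data.table`
#'   with `cluster_id`, `S`, `df`, `p_value`, `replicable`), `run_stats`
#'   (clusters x runs matrix), `pairings`, `alpha`.
#' @export
replication_test <- function(clusters, samples, n_runs = 10L, alpha = 0.05,
                             seed = 1L) {
  samples <- data.table::as.data.table(samples)
  pairings <- draw_pairings(samples, n_runs = n_runs, seed = seed)
  P <- presence_matrix(clusters, samples$sample_id)
  stats <- run_statistics(P, pairings)
  comb <- combined_test(stats, alpha = alpha)
  res <- data.table::data.table(cluster_id = clusters$clusters$cluster_id,
                                comb)
  structure(list(results = res, run_stats = stats, pairings = pairings,
                 alpha = alpha), class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat("<replication_result> ", nrow(x$results), " clusters, df = ",
      x$results$df[1] %||% NA, "; ", sum(x$results$replicable),
      " replicable at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Select replicable clusters
#'
#' @param result a `replication_result` (or its `results` table).
#' @param alpha threshold; clusters with `p_value <= alpha` are retained.
#' @return vector of replicable `cluster_id`s.
#' @export
filter_replicable <- function(result, alpha = 0.05) {
  abort_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  res <- if (inherits(result, "replication_result")) result$results else
    data.table::as.data.table(result)
  res$cluster_id[res$p_value <= alpha]
}

#' Count clusters in a p-value window
#'
#' Number of clusters with `lo < p_value <= hi`; used for threshold
#' sensitivity reports (how many additional clusters a slightly more lenient
#' threshold would admit).
#'
#' @param result a `replication_result` (or its `results` table).
#' @param lo,hi window bounds (half-open on the left).
#' @return integer count.
#' @export
count_in_window <- function(result, lo, hi) {
  res <- if (inherits(result, "replication_result")) result$results else
    data.table::as.data.table(result)
  sum(res$p_value > lo & res$p_value <= hi)
}

# Rank (Wilcoxon) AUC of scores against binary labels; ties handled by
# midranks. NA when the labels are all one class.
rank_auc <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stability of the replicable set in the number of runs
#'
#' Draws `max_runs` pairings, takes the replicable set from combining all
#' `max_runs` runs as the reference labels, and for every `N` in
#' `1..max_runs-1` computes the ROC AUC of the `N`-run combined p-values
#' (combined with df = N) against those labels. Used to judge how many runs
#' are needed for a stable replicable set.
#'
#' @inheritParams replication_test
#' @param max_runs total number of runs drawn (default 20).
#' @return `data.table` with `n_runs` and `auc` (NA when the reference
#'   labels are all one class).
#' @export
stability_analysis <- function(clusters, samples, max_runs = 20L,
                               alpha = 0.05, seed = 1L) {
  samples <- data.table::as.data.table(samples)
  pairings <- draw_pairings(samples, n_runs = max_runs, seed = seed)
  P <- presence_matrix(clusters, samples$sample_id)
  stats <- run_statistics(P, pairings)
  ref <- combined_test(stats, alpha = alpha)$replicable
  out <- data.table::data.table(n_runs = seq_len(max_runs - 1L), auc = NA_real_)
  if (all(ref) || !any(ref)) {
    warning("reference labels are all one class; AUC undefined")
    return(out[])
  }
  for (N in seq_len(max_runs - 1L)) {
    pN <- combined_test(stats[, seq_len(N), drop = FALSE], alpha = alpha)$p_value
    out$auc[N] <- rank_auc(-pN, ref)
  }
  out[]
}

#' Export replication results as TSV
#'
#' @param result a `replication_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_replication <- function(result, path) {
  stopifnot(inherits(result, "replication_result"))
  stats <- result$run_stats
  colnames(stats) <- sprintf("stat_run%02d", seq_len(ncol(stats)))
  data.table::fwrite(cbind(result$results, data.table::as.data.table(stats)),
                     path, sep = "\t")
  invisible(path)
}

#' Maximum-likelihood degrees of freedom of a chi-squared sample
#'
#' Fits the df of a central chi-squared distribution to a sample by
#' maximizing the log-likelihood (one-dimensional search). Used to verify
#' the calibration of the replication statistics.
#'
#' @param x non-negative statistics; exact zeros are floored at a tiny
#'   positive value so the likelihood stays finite.
#' @param interval search interval for df.
#' @return fitted df (numeric scalar).
#' @export
fit_chisq_df <- function(x, interval = c(0.05, 100)) {
  abort_if(any(x < 0), "chi-squared statistics must be non-negative")
  x <- pmax(x, 1e-12)
  nll <- function(df) -sum(stats::dchisq(x, df = df, log = TRUE))
  stats::optimize(nll, interval)$minimum
}
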