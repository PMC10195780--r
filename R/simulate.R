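# Synthetic peak-call datasets with known ground truth. The generator
# emulates the statistical structure the pipeline assumes: a set of true
# regulatory sites, each active in a random subset of cell types, observed in
# every replicate of an active cell type (up to dropout) with jittered
# boundaries and batch-distorted intensities; plus spurious peaks that appear
# in exactly one sample each. Everything is driven by one master seed, so a
# given configuration always produces byte-identical files.

#' Configuration of the synthetic DHS dataset generator
#'
#' Defaults describe a desk-scale study: 20 cell types with 2-4 replicates
#' each, two generating centers (batches), 2,000 true regulatory sites with
#' log-normal lengths (median ~310 bp), and 2,000 spurious single-sample
#' peaks per sample. Batch distortion is a monotone power-plus-scale
#' transform of the intensity, the class of effect the rank-based
#' normalization is designed to remove.
#'
#' @param n_cell_types number of cell types.
#' @param replicates_range inclusive range the per-cell-type replicate count
#'   is drawn from.
#' @param n_batches number of generating centers; replicates are assigned
#'   round-robin within each cell type, so cell types with several replicates
#'   span batches (as when two consortia assay the same cell type).
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_true_sites number of true regulatory sites.
#' @param length_meanlog,length_sdlog log-normal site-length parameters
#'   (defaults give a median length of 310 bp).
#' @param activity_prob probability a true site is active in a given cell
#'   type (each site is guaranteed active in at least one).
#' @param jitter_sd s.d. (bp) of the Gaussian jitter added independently to
#'   each peak boundary.
#' @param intensity_range range of the site-level base intensity, on the
#'   -log10(p) scale of the peak caller.
#' @param intensity_noise_sd s.d. of the multiplicative log-normal noise on
#'   observed intensities.
#' @param batch_power,batch_scale per-batch monotone distortion:
#'   observed = scale * base^power (recycled over batches).
#' @param dropout_rate probability an active site fails to be called in a
#'   given replicate.
#' @param spurious_per_sample number of spurious peaks per sample.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 20L,
                       replicates_range = c(2L, 4L),
                       n_batches = 2L,
                       chrom_lengths = c(chr1 = 60e6, chr2 = 60e6),
                       n_true_sites = 2000L,
                       length_meanlog = log(310), length_sdlog = 0.35,
                       activity_prob = 0.3,
                       jitter_sd = 25,
                       intensity_range = c(10, 25),
                       intensity_noise_sd = 0.1,
                       batch_power = c(1.0, 1.4),
                       batch_scale = c(1.0, 0.6),
                       dropout_rate = 0.05,
                       spurious_per_sample = 2000L,
                       seed = 1L) {
  abort_if(n_cell_types < 1 || n_true_sites < 0 || n_batches < 1,
           "counts must be positive")
  abort_if(activity_prob < 0 || activity_prob > 1 ||
             dropout_rate < 0 || dropout_rate > 1,
           "probabilities must be in [0, 1]")
  chrom_lengths <- unlist(chrom_lengths) # YAML configs arrive as lists
  abort_if(is.null(names(chrom_lengths)), "chrom_lengths must be named")
  structure(as.list(environment()), class = "sim_config")
}

# place n non-overlapping intervals of the given lengths uniformly on one
# chromosome, keeping `gap` bp of clearance; errors if they cannot fit
place_nonoverlapping <- function(lengths, chrom_len, gap) {
  n <- length(lengths)
  if (n == 0L) return(integer(0))
  slack <- chrom_len - sum(lengths) - gap * (n + 1)
  abort_if(slack <= 0, "sites do not fit on the chromosome; ",
           "reduce n_true_sites or enlarge the genome")
  cuts <- sort(stats::runif(n, 0, slack))
  ord <- sample.int(n) # random order of lengths along the chromosome
  starts <- integer(n)
  starts[ord] <- as.integer(floor(cuts + gap +
                                    cumsum(c(0, lengths[ord][-n])) +
                                    gap * (seq_len(n) - 1L)))
  starts
}

#' Generate a synthetic DHS peak-call dataset with ground truth
#'
#' Writes one narrowPeak file per sample plus `metadata.tsv` and `truth.tsv`
#' into `out_dir`, in exactly the formats [read_narrowpeak()] and
#' [read_metadata()] consume. True sites yield a peak in every replicate of
#' every active cell type (minus dropout), with jittered boundaries and
#' batch-distorted intensities; spurious peaks are placed at positions that
#' overlap nothing else and each appears in exactly one sample.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return list: `metadata` (`data.table`), `truth` (`data.table` of sites
#'   with `site_id`, `chrom`, `start`, `end`, `kind` = "true"/"spurious",
#'   `active_cell_types`, `base_intensity`, `sample_id` for spurious peaks),
#'   `dir`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(out_dir, "peaks"), recursive = TRUE,
             showWarnings = FALSE)
  cfg <- config
  with_seed(derive_seed(cfg$seed, 7919L), {
    # --- samples and batches ---------------------------------------------
    cts <- sprintf("celltype%02d", seq_len(cfg$n_cell_types))
    n_rep <- sample(seq(cfg$replicates_range[1], cfg$replicates_range[2]),
                    cfg$n_cell_types, replace = TRUE)
    meta <- data.table::rbindlist(lapply(seq_len(cfg$n_cell_types), function(i) {
      data.table::data.table(
        sample_id = sprintf("%s_rep%d", cts[i], seq_len(n_rep[i])),
        cell_type = cts[i],
        donor_id = sprintf("donor_%s_%d", cts[i], seq_len(n_rep[i])),
        project = sprintf("center%d",
                          (seq_len(n_rep[i]) - 1L) %% cfg$n_batches + 1L))
    }))
    meta$path <- file.path("peaks", paste0(meta$sample_id, ".narrowPeak"))
    n_samp <- nrow(meta)

    # --- true sites -------------------------------------------------------
    chroms <- names(cfg$chrom_lengths)
    site_chrom <- sample(chroms, cfg$n_true_sites, replace = TRUE,
                         prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
    site_len <- pmax(50L, as.integer(round(stats::rlnorm(
      cfg$n_true_sites, cfg$length_meanlog, cfg$length_sdlog))))
    gap <- as.integer(ceiling(8 * cfg$jitter_sd))
    site_start <- integer(cfg$n_true_sites)
    for (chr in chroms) {
      idx <- which(site_chrom == chr)
      site_start[idx] <- place_nonoverlapping(site_len[idx],
                                              cfg$chrom_lengths[[chr]], gap)
    }
    active <- matrix(stats::runif(cfg$n_true_sites * cfg$n_cell_types) <
                       cfg$activity_prob,
                     cfg$n_true_sites, cfg$n_cell_types)
    for (i in which(rowSums(active) == 0L))
      active[i, sample.int(cfg$n_cell_types, 1L)] <- TRUE
    base_int <- stats::runif(cfg$n_true_sites,
                             cfg$intensity_range[1], cfg$intensity_range[2])
    truth_true <- data.table::data.table(
      site_id = sprintf("site%05d", seq_len(cfg$n_true_sites)),
      chrom = site_chrom, start = site_start,
      end = site_start + site_len, kind = "true",
      active_cell_types = vapply(seq_len(cfg$n_true_sites), function(i)
        paste(cts[active[i, ]], collapse = ","), character(1)),
      base_intensity = base_int, sample_id = "")

    # --- spurious peaks: globally non-overlapping singleton positions ----
    n_spur <- cfg$spurious_per_sample * n_samp
    spur <- make_spurious(cfg, truth_true, n_spur, gap)
    spur$sample_id <- rep(meta$sample_id, each = cfg$spurious_per_sample)
    spur$site_id <- sprintf("spur%06d", seq_len(nrow(spur)))

    # --- emit per-sample peak files --------------------------------------
    batch_of_sample <- as.integer(sub("^center", "", meta$project))
    pw <- cfg$batch_power[(batch_of_sample - 1L) %% length(cfg$batch_power) + 1L]
    sc <- cfg$batch_scale[(batch_of_sample - 1L) %% length(cfg$batch_scale) + 1L]
    for (s in seq_len(n_samp)) {
      ct_i <- match(meta$cell_type[s], cts)
      on <- which(active[, ct_i])
      keep <- on[stats::runif(length(on)) >= cfg$dropout_rate]
      js <- as.integer(round(stats::rnorm(length(keep), 0, cfg$jitter_sd)))
      je <- as.integer(round(stats::rnorm(length(keep), 0, cfg$jitter_sd)))
      st <- pmax(0L, site_start[keep] + js)
      en <- pmax(st + 50L, site_start[keep] + site_len[keep] + je)
      raw <- base_int[keep] * exp(stats::rnorm(length(keep), 0,
                                               cfg$intensity_noise_sd))
      obs <- sc[s] * raw ^ pw[s]
      sp <- spur[spur$sample_id == meta$sample_id[s]]
      sp_raw <- sp$base_intensity * exp(stats::rnorm(nrow(sp), 0,
                                                     cfg$intensity_noise_sd))
      sp_obs <- sc[s] * sp_raw ^ pw[s]
      dt <- data.table::data.table(
        chrom = c(site_chrom[keep], sp$chrom),
        start = c(st, sp$start), end = c(en, sp$end),
        name = ".", score = 0L, strand = ".",
        signal = round(c(obs, sp_obs), 4),
        pval = round(c(obs, sp_obs), 4), qval = -1, summit = -1L)
      data.table::setorder(dt, chrom, start, end)
      data.table::fwrite(dt, file.path(out_dir, meta$path[s]),
                         sep = "\t", col.names = FALSE)
    }
    truth <- data.table::rbindlist(list(truth_true, spur[, names(truth_true),
                                                         with = FALSE]))
    data.table::fwrite(meta, file.path(out_dir, "metadata.tsv"), sep = "\t")
    data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
    list(metadata = meta, truth = truth, dir = out_dir)
  })
}

# draw spurious peak positions that overlap neither the true sites nor each
# other; batched rejection sampling with a retry budget
make_spurious <- function(cfg, truth_true, n_spur, gap) {
  if (n_spur == 0L) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      kind = character(), active_cell_types = character(),
      base_intensity = numeric()))
  }
  chroms <- names(cfg$chrom_lengths)
  occupied <- lapply(chroms, function(chr) {
    tt <- truth_true[truth_true$chrom == chr]
    IRanges::IRanges(start = tt$start + 1L - gap, end = tt$end + gap)
  })
  names(occupied) <- chroms
  got <- list()
  n_left <- n_spur
  for (try in seq_len(50L)) {
    if (n_left <= 0L) break
    n_prop <- ceiling(n_left * 1.3)
    chr <- sample(chroms, n_prop, replace = TRUE,
                  prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
    len <- pmax(50L, as.integer(round(stats::rlnorm(
      n_prop, cfg$length_meanlog, cfg$length_sdlog))))
    start <- as.integer(floor(stats::runif(
      n_prop, 0, cfg$chrom_lengths[chr] - len)))
    cand <- data.table::data.table(chrom = chr, start = start,
                                   end = start + len)
    ok <- rep(TRUE, n_prop)
    for (c2 in chroms) {
      idx <- which(cand$chrom == c2)
      if (length(idx) == 0L) next
      ir <- IRanges::IRanges(cand$start[idx] + 1L, cand$end[idx])
      ok[idx[IRanges::countOverlaps(ir, occupied[[c2]]) > 0L]] <- FALSE
      # reject candidates that overlap an earlier accepted candidate
      self <- IRanges::findOverlaps(ir, drop.self = TRUE)
      dup <- unique(S4Vectors::queryHits(self)[
        S4Vectors::queryHits(self) > S4Vectors::subjectHits(self)])
      ok[idx[dup]] <- FALSE
    }
    cand <- cand[ok]
    if (nrow(cand) > n_left) cand <- cand[seq_len(n_left)]
    got[[try]] <- cand
    n_left <- n_left - nrow(cand)
    # extend the occupied set with what we accepted
    for (c2 in chroms) {
      acc <- cand[cand$chrom == c2]
      if (nrow(acc) > 0L)
        occupied[[c2]] <- c(occupied[[c2]],
                            IRanges::IRanges(acc$start + 1L, acc$end))
    }
  }
  abort_if(n_left > 0L,
           "could not place all spurious peaks within the retry budget")
  out <- data.table::rbindlist(got)
  out$kind <- "spurious"
  out$active_cell_types <- ""
  out$base_intensity <- stats::runif(nrow(out), cfg$intensity_range[1],
                                     cfg$intensity_range[2])
  out
}

#' Compare pipeline output against the simulation ground truth
#'
#' A replicable cluster matches a true site when their spans overlap
#' reciprocally by at least 50% or their centers lie within `tolerance_bp`.
#' Reports site-level precision (matched replicable clusters / replicable
#' clusters), recall (matched true sites / true sites) and the spurious pass
#' rate (fraction of clusters overlapping no true site that were flagged
#' replicable).
#'
#' @param clusters the `dhs_clusters` object from [cluster_peaks()].
#' @param replicable_ids cluster ids flagged replicable (or kept in the
#'   final matrix).
#' @param truth the truth table from [simulate_dataset()].
#' @param tolerance_bp center-distance tolerance for a match (default 100).
#' @return list with `precision`, `recall`, `spurious_pass_rate`,
#'   `n_replicable`, `n_true_sites`, `n_spurious_clusters`.
#' @export
evaluate_recovery <- function(clusters, replicable_ids, truth,
                              tolerance_bp = 100) {
  truth <- data.table::as.data.table(truth)
  abort_if(nrow(truth) == 0L, "empty truth table")
  true_sites <- truth[truth$kind == "true"]
  spans <- clusters$clusters
  match_mat <- match_sites(spans, true_sites, tolerance_bp)
  is_rep <- spans$cluster_id %in% replicable_ids
  cl_matched <- match_mat$cluster_matched
  site_matched_by_rep <- unique(match_mat$pairs$site[
    match_mat$pairs$cluster %in% which(is_rep)])
  n_rep <- sum(is_rep)
  precision <- if (n_rep == 0L) NA_real_ else
    sum(cl_matched & is_rep) / n_rep
  recall <- if (nrow(true_sites) == 0L) NA_real_ else
    length(site_matched_by_rep) / nrow(true_sites)
  spurious_cl <- !cl_matched
  spr <- if (sum(spurious_cl) == 0L) NA_real_ else
    sum(spurious_cl & is_rep) / sum(spurious_cl)
  list(precision = precision, recall = recall, spurious_pass_rate = spr,
       n_replicable = n_rep, n_true_sites = nrow(true_sites),
       n_spurious_clusters = sum(spurious_cl))
}

# reciprocal-50%-overlap or center-distance matching between cluster spans
# and true sites
match_sites <- function(spans, true_sites, tolerance_bp) {
  pairs <- list()
  for (chr in unique(spans$chrom)) {
    ci <- which(spans$chrom == chr)
    si <- which(true_sites$chrom == chr)
    if (length(si) == 0L || length(ci) == 0L) next
    ir_c <- IRanges::IRanges(spans$start[ci] + 1L, spans$end[ci])
    ir_s <- IRanges::IRanges(true_sites$start[si] + 1L, true_sites$end[si])
    hits <- IRanges::findOverlaps(ir_c, ir_s,
                                  maxgap = as.integer(tolerance_bp))
    qi <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
    inter <- pmin(spans$end[ci][qi], true_sites$end[si][sj]) -
      pmax(spans$start[ci][qi], true_sites$start[si][sj])
    len_c <- spans$end[ci][qi] - spans$start[ci][qi]
    len_s <- true_sites$end[si][sj] - true_sites$start[si][sj]
    recip <- inter >= 0.5 * len_c & inter >= 0.5 * len_s
    cen_c <- (spans$start[ci][qi] + spans$end[ci][qi]) / 2
    cen_s <- (true_sites$start[si][sj] + true_sites$end[si][sj]) / 2
    near <- abs(cen_c - cen_s) <= tolerance_bp
    keep <- recip | near
    pairs[[chr]] <- data.table::data.table(cluster = ci[qi][keep],
                                           site = si[sj][keep])
  }
  pairs <- if (length(pairs)) data.table::rbindlist(pairs) else
    data.table::data.table(cluster = integer(), site = integer())
  cluster_matched <- seq_len(nrow(spans)) %in% pairs$cluster
  list(pairs = pairs, cluster_matched = cluster_matched)
}

#' Simulate null presence patterns for calibration studies
#'
#' Builds the null used to check the calibration of the replication test:
#' `n_clusters` clusters over `n_cell_types` cell types with `n_replicates`
#' replicates each, where every replicate of every cell type is present
#' independently with a per-cluster Bernoulli margin drawn uniformly from
#' `p_range`. There is no replicate concordance beyond chance, so the
#' single-run statistic should follow chi-squared(1).
#'
#' @param n_clusters number of null clusters.
#' @param n_cell_types number of cell types (default 161).
#' @param n_replicates replicates per cell type (default 4).
#' @param p_range range of the per-cluster presence probability.
#' @param seed seed.
#' @return list: `presence` (clusters x samples logical matrix) and
#'   `metadata` (`data.table` with `sample_id`, `cell_type`, `donor_id`,
#'   `project`).
#' @export
simulate_null_presence <- function(n_clusters, n_cell_types = 161L,
                                   n_replicates = 4L, p_range = c(0.2, 0.8),
                                   seed = 1L) {
  meta <- data.table::data.table(
    cell_type = rep(sprintf("ct%03d", seq_len(n_cell_types)),
                    each = n_replicates),
    rep = rep(seq_len(n_replicates), n_cell_types))
  meta[, sample_id := sprintf("%s_rep%d", cell_type, rep)]
  meta[, donor_id := sample_id]
  meta[, project := "null"]
  meta[, rep := NULL]
  with_seed(derive_seed(seed, 15485863L), {
    p <- stats::runif(n_clusters, p_range[1], p_range[2])
    P <- matrix(stats::runif(n_clusters * nrow(meta)) < p,
                n_clusters, nrow(meta))
  })
  colnames(P) <- meta$sample_id
  list(presence = P, metadata = meta[])
}

#' Replication test on a raw presence matrix
#'
#' Same computation as [replication_test()] but starting from an explicit
#' presence matrix instead of a `dhs_clusters` object; used for calibration
#' simulations.
#'
#' @param P logical presence matrix (clusters x samples), columns named by
#'   sample.
#' @param samples metadata with `sample_id` and `cell_type`.
#' @inheritParams replication_test
#' @return same structure as [replication_test()] with `cluster_id` equal to
#'   the row index.
#' @export
replication_test_presence <- function(P, samples, n_runs = 10L, alpha = 0.05,
                                      seed = 1L) {
  pairings <- draw_pairings(samples, n_runs = n_runs, seed = seed)
  stats <- run_statistics(P, pairings)
  comb <- combined_test(stats, alpha = alpha)
  res <- data.table::data.table(cluster_id = seq_len(nrow(P)), comb)
  structure(list(results = res, run_stats = stats, pairings = pairings,
                 alpha = alpha), class = "replication_result")
}
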