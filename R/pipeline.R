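# End-to-end orchestration: qc -> cluster -> reptest -> normalize -> export.
# Every stage writes its artifact (plus a checksum of the configuration) into
# the run directory, so a rerun with an identical configuration can resume
# after the stages whose artifacts are already present and current.

#' Pipeline configuration
#'
#' Defaults are the published operating point of the method: peak-count
#' window 40,000-500,000, MCL defaults, 10 replication runs at alpha 0.05,
#' 10,000-site quantile-normalization subsample, activity threshold 0.25.
#'
#' @param metadata path to the metadata TSV.
#' @param peak_dir directory peak paths are resolved against.
#' @param out_dir run directory for artifacts.
#' @param min_peaks,max_peaks sample peak-count window.
#' @param mcl an [mcl_params()] list.
#' @param n_runs replication runs.
#' @param alpha replication significance threshold.
#' @param n_subsample quantile-normalization subsample size.
#' @param activity_threshold final per-cell-type activity cutoff.
#' @param autosomes_only restrict to autosomes.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(metadata, peak_dir, out_dir,
                            min_peaks = 40000, max_peaks = 500000,
                            mcl = mcl_params(), n_runs = 10L, alpha = 0.05,
                            n_subsample = 10000L, activity_threshold = 0.25,
                            autosomes_only = TRUE, seed = 1L) {
  abort_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  abort_if(activity_threshold < 0 || activity_threshold >= 1,
           "activity_threshold must be in [0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `mcl` may be a
#' nested mapping of [mcl_params()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$mcl)) y$mcl <- do.call(mcl_params, y$mcl)
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[sort(names(config))]), f)
  unname(tools::md5sum(f))
}

stage_current <- function(path, hash_file, hash) {
  file.exists(path) && file.exists(hash_file) &&
    identical(readLines(hash_file, n = 1L), hash)
}

mark_stage <- function(hash_file, hash) writeLines(hash, hash_file)

#' Run the full pipeline
#'
#' Executes qc, clustering, the replication test, intensity normalization and
#' the exports in order, writing each stage's artifact into the run
#' directory. A rerun with an identical configuration reuses artifacts of
#' completed stages (checksum match) unless `resume = FALSE`.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse current stage artifacts when present (default TRUE).
#' @return list with the QC report, clusters, replication result, matrices
#'   and the final `cell_type_matrix`, invisibly.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  art <- function(name) file.path(config$out_dir, name)
  log_stage <- function(...) message("[dhsatlas] ", ...)

  # --- qc -----------------------------------------------------------------
  qc_rds <- art("qc.rds")
  if (resume && stage_current(qc_rds, art("qc.ok"), hash)) {
    log_stage("qc: reusing artifact")
    qc <- readRDS(qc_rds)
  } else {
    meta <- read_metadata(config$metadata)
    peaks <- read_all_peaks(meta, config$peak_dir,
                            autosomes_only = config$autosomes_only)
    counts <- table(peaks$sample_id)
    peak_counts <- stats::setNames(as.integer(counts), names(counts))
    report <- qc_samples(meta, peak_counts,
                         config$min_peaks, config$max_peaks)
    qc <- list(report = report,
               peaks = peaks[peaks$sample_id %in% report$passed$sample_id])
    log_stage("qc: ", report$n_input, " samples in, ",
              report$n_passed, " passed, ",
              nrow(qc$peaks), " peaks retained")
    saveRDS(qc, qc_rds)
    export_qc_report(report, art("qc_removed.tsv"))
    mark_stage(art("qc.ok"), hash)
  }

  # --- cluster ------------------------------------------------------------
  cl_rds <- art("clusters.rds")
  if (resume && stage_current(cl_rds, art("cluster.ok"), hash)) {
    log_stage("cluster: reusing artifact")
    clusters <- readRDS(cl_rds)
  } else {
    clusters <- cluster_peaks(qc$peaks, config$mcl)
    log_stage("cluster: ", nrow(qc$peaks), " peaks -> ",
              nrow(clusters$clusters), " DHS clusters")
    saveRDS(clusters, cl_rds)
    export_bed(clusters, art("clusters.bed"))
    export_membership(clusters, art("membership.tsv"))
    mark_stage(art("cluster.ok"), hash)
  }

  # --- reptest ------------------------------------------------------------
  rep_rds <- art("replication.rds")
  if (resume && stage_current(rep_rds, art("reptest.ok"), hash)) {
    log_stage("reptest: reusing artifact")
    repres <- readRDS(rep_rds)
  } else {
    repres <- replication_test(clusters, qc$report$passed,
                               n_runs = config$n_runs, alpha = config$alpha,
                               seed = derive_seed(config$seed, 1L))
    log_stage("reptest: ", sum(repres$results$replicable), "/",
              nrow(repres$results), " clusters replicable at alpha = ",
              config$alpha)
    saveRDS(repres, rep_rds)
    export_replication(repres, art("replication.tsv"))
    mark_stage(art("reptest.ok"), hash)
  }

  # --- normalize ----------------------------------------------------------
  norm_rds <- art("normalized.rds")
  if (resume && stage_current(norm_rds, art("normalize.ok"), hash)) {
    log_stage("normalize: reusing artifact")
    norm <- readRDS(norm_rds)
  } else {
    rep_ids <- filter_replicable(repres, config$alpha)
    raw <- assign_intensities(clusters, qc$report$passed$sample_id,
                              cluster_ids = rep_ids)
    scaled <- scale_per_sample(raw)
    qn <- quantile_normalize(scaled, n_subsample = config$n_subsample,
                             seed = derive_seed(config$seed, 2L))
    ct <- collapse_by_celltype(qn, qc$report$passed, clusters$clusters)
    final <- filter_active(ct, config$activity_threshold)
    norm <- list(raw = raw, scaled = scaled, normalized = qn,
                 cell_type = ct, final = final)
    log_stage("normalize: ", nrow(final$values), "/", nrow(ct$values),
              " replicable sites active above ", config$activity_threshold)
    saveRDS(norm, norm_rds)
    mark_stage(art("normalize.ok"), hash)
  }

  # --- export -------------------------------------------------------------
  if (!(resume && stage_current(art("final_matrix.tsv"),
                                art("export.ok"), hash))) {
    export_matrix(norm$final, art("final_matrix.tsv"))
    export_gff3(norm$final, art("gff3"))
    final_spans <- norm$final$spans
    export_bed(final_spans, art("final_sites.bed"))
    manifest <- list(
      package = "dhsatlas",
      version = as.character(utils::packageVersion("dhsatlas")),
      seed = config$seed, alpha = config$alpha, n_runs = config$n_runs,
      n_subsample = config$n_subsample,
      activity_threshold = config$activity_threshold,
      config_hash = hash,
      n_samples_passed = qc$report$n_passed,
      n_peaks = nrow(qc$peaks),
      n_clusters = nrow(clusters$clusters),
      n_replicable = sum(repres$results$replicable),
      n_final_sites = nrow(norm$final$values))
    yaml::write_yaml(manifest, art("manifest.yaml"))
    log_stage("export: wrote final matrix, BED, GFF3 and manifest")
    mark_stage(art("export.ok"), hash)
  } else {
    log_stage("export: reusing artifact")
  }

  invisible(list(qc = qc$report, clusters = clusters, replication = repres,
                 matrices = norm, final = norm$final))
}
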