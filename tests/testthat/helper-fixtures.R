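# Shared fixture builders. Everything is generated in code at test time.

write_np_lines <- function(lines, path = tempfile(fileext = ".narrowPeak")) {
  writeLines(lines, path)
  path
}

np_line <- function(chrom, start, end, signal = 5, pval = 7,
                    qval = -1, summit = -1) {
  paste(chrom, start, end, ".", 0, ".", signal, pval, qval, summit, sep = "\t")
}

write_metadata_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

toy_metadata <- function() {
  data.table::data.table(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    cell_type = c("A", "A", "B", "B", "B", "C"),
    donor_id = paste0("d", 1:6),
    project = rep(c("p1", "p2"), 3),
    path = paste0("s", 1:6, ".narrowPeak"))
}

# peaks table builder with defaults
peaks_dt <- function(chrom, start, end, sample_id = "s1", neglog10_p = 5) {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), signal = neglog10_p,
                         neglog10_p = neglog10_p, sample_id = sample_id)
}

# random peaks on one chromosome for graph property tests
random_chrom_peaks <- function(n, chrom = "chr1", max_pos = 10000,
                               len_range = c(50, 400)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  peaks_dt(chrom, start, start + len,
           sample_id = paste0("s", sample.int(5, n, replace = TRUE)))
}

# independent reference MCL: dense, no pruning, plain iteration
reference_mcl <- function(A, self_loop = 1, inflation = 2, iters = 200) {
  diag(A) <- diag(A) + self_loop
  M <- A %*% diag(1 / colSums(A))
  for (i in seq_len(iters)) {
    M2 <- (M %*% M)^inflation
    M2 <- M2 %*% diag(1 / colSums(M2))
    if (max(abs(M2 - M)) < 1e-10) { M <- M2; break }
    M <- M2
  }
  memb <- rep(NA_integer_, nrow(M))
  lab <- 0L
  for (i in which(diag(M) > 1e-6)) {
    s <- which(M[i, ] > 1e-6)
    if (all(!is.na(memb[s]))) next
    lab <- lab + 1L
    memb[s] <- lab
  }
  memb
}

# the bridged two-clique fixture: two 3-cliques (internal weight 0.9)
# joined by a single 0.05 edge
bridged_cliques <- function() {
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    A[p[1], p[2]] <- A[p[2], p[1]] <- 0.9
  A[3, 4] <- A[4, 3] <- 0.05
  A
}

# small simulated dataset reused by pipeline tests
small_sim_config <- function(seed = 11) {
  sim_config(n_cell_types = 4L, n_true_sites = 60L,
             spurious_per_sample = 30L, chrom_lengths = c(chr1 = 3e6),
             seed = seed)
}
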