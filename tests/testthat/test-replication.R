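test_that("pairings cover exactly the cell types with >= 2 replicates", {
  md <- toy_metadata() # A: 2 reps, B: 3 reps, C: 1 rep
  pr <- draw_pairings(md, n_runs = 10, seed = 1)
  expect_length(pr, 10L)
  for (p in pr) {
    expect_setequal(p$cell_type, c("A", "B"))   # C excluded
    expect_true(all(p$s1 != p$s2))
    expect_equal(unname(sort(unlist(p[cell_type == "A", c("s1", "s2")]))),
                 c("s1", "s2"))                 # only one pair exists for A
  }
  expect_error(draw_pairings(md[cell_type == "C"], seed = 1),
               "at least two")
  # same seed, same pairings
  expect_identical(pr, draw_pairings(md, n_runs = 10, seed = 1))
})

test_that("pair draws are uniform over the three pairs of a triple", {
  md <- data.table::data.table(sample_id = c("a", "b", "c"), cell_type = "t")
  pr <- draw_pairings(md, n_runs = 30000, seed = 3)
  lab <- vapply(pr, function(p) paste(sort(c(p$s1, p$s2)), collapse = "-"), "")
  freq <- table(lab) / length(lab)
  expect_setequal(names(freq), c("a-b", "a-c", "b-c"))
  expect_true(all(abs(freq - 1 / 3) < 0.01))
})

test_that("presence tables match hand enumeration", {
  pairing <- data.table::data.table(
    cell_type = c("A", "B", "C", "D"),
    s1 = c("a1", "b1", "c1", "d1"), s2 = c("a2", "b2", "c2", "d2"))
  # present in both A replicates, first of B, second of C, neither of D
  tab <- presence_table(c("a1", "a2", "b1", "c2"), pairing)
  expect_equal(tab, c(n11 = 1L, n10 = 1L, n01 = 1L, n00 = 1L))
  expect_equal(presence_table(c("a1", "a2", "b1", "b2", "c1", "c2",
                                "d1", "d2"), pairing),
               c(n11 = 4L, n10 = 0L, n01 = 0L, n00 = 0L))
  expect_equal(presence_table(character(0), pairing),
               c(n11 = 0L, n10 = 0L, n01 = 0L, n00 = 4L))
})

test_that("the single-run statistic reproduces closed-form values", {
  expect_equal(single_run_statistic(50, 0, 0, 50), 100)
  expect_equal(single_run_statistic(25, 25, 25, 25), 0)
  expect_equal(single_run_statistic(30, 20, 20, 30), 4)
  # degenerate conventions
  expect_equal(single_run_statistic(7, 0, 0, 0), 7)   # all present -> T
  expect_equal(single_run_statistic(0, 0, 0, 9), 0)   # all absent -> 0
  expect_equal(single_run_statistic(3, 4, 0, 0), 0)   # constant margin -> 0
  expect_equal(single_run_statistic(0, 5, 5, 0), 10)  # anti-concordance scores
  expect_error(single_run_statistic(-1, 0, 0, 5), "non-negative")
  # swapping the replicates of every pair leaves the statistic unchanged
  withr::with_seed(2, {
    n <- matrix(rpois(400, 8), ncol = 4)
    expect_equal(single_run_statistic(n[, 1], n[, 2], n[, 3], n[, 4]),
                 single_run_statistic(n[, 1], n[, 3], n[, 2], n[, 4]))
  })
})

test_that("moving discordant mass to concordant never lowers the statistic", {
  # shift n10 -> n11 while margins stay non-degenerate, association positive
  s_prev <- -Inf
  for (k in 0:19) {
    s <- single_run_statistic(30 + k, 20 - k, 15, 35)
    expect_gte(s, s_prev)
    s_prev <- s
  }
})

test_that("combined test sums runs against a chi-squared(K) reference", {
  expect_equal(combined_test(rep(0, 10))$p_value, 1)
  expect_false(combined_test(rep(0, 10))$replicable)
  # classic chi-squared(10) 5% critical value sits exactly on the boundary
  expect_equal(combined_test(c(18.307, rep(0, 9)))$p_value, 0.05,
               tolerance = 1e-3)
  ct <- combined_test(c(stats::qchisq(0.95, 10), rep(0, 9)))
  expect_equal(ct$p_value, 0.05, tolerance = 1e-12)
  expect_true(ct$replicable) # p <= alpha is inclusive
  # constitutive cluster: present everywhere in every run
  big <- combined_test(rep(161, 10))
  expect_lt(big$p_value, 1e-300)
  expect_true(big$replicable)
  expect_error(combined_test(matrix(0, 1, 0)), "at least one run")
  expect_error(combined_test(rep(1, 10), alpha = 0), "alpha")
})

test_that("replicable selection is inclusive and windows count correctly", {
  res <- data.table::data.table(cluster_id = 1:5, S = 0, df = 10,
                                p_value = c(0.01, 0.05, 0.0501, 0.0505, 0.9))
  expect_equal(filter_replicable(res, 0.05), 1:2)
  expect_equal(count_in_window(res, 0.05, 0.05), 0L)   # empty window
  expect_equal(count_in_window(res, 0.05, 0.0501), 1L)
  expect_equal(count_in_window(res, 0.05, 0.0505), 2L)
  # linear-scan oracle on random p-values
  withr::with_seed(8, {
    p <- runif(500)
    rr <- data.table::data.table(cluster_id = 1:500, S = 0, df = 10,
                                 p_value = p)
    for (w in list(c(0.1, 0.3), c(0, 1), c(0.5, 0.5))) {
      expect_equal(count_in_window(rr, w[1], w[2]),
                   sum(p > w[1] & p <= w[2]))
    }
  })
})

test_that("null presence gives chi-squared(1) single-run statistics", {
  null <- simulate_null_presence(2000, n_cell_types = 161, n_replicates = 4,
                                 seed = 21)
  pr <- draw_pairings(null$metadata, n_runs = 1, seed = 22)
  s1 <- dhsatlas:::run_statistics(null$presence, pr)[, 1]
  expect_equal(fit_chisq_df(s1), 1, tolerance = 0.1)
  ks <- suppressWarnings(stats::ks.test(s1, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("strongly concordant clusters are flagged far above alpha", {
  null <- simulate_null_presence(500, n_cell_types = 30, n_replicates = 2,
                                 seed = 31)
  # copy one replicate's presence onto the other: perfect concordance
  P <- null$presence
  cts <- unique(null$metadata$cell_type)
  for (ct in cts) {
    ids <- null$metadata$sample_id[null$metadata$cell_type == ct]
    P[, ids[2]] <- P[, ids[1]]
  }
  res <- replication_test_presence(P, null$metadata, n_runs = 10, seed = 32)
  expect_gt(mean(res$results$replicable), 0.95)
  # and the null itself stays near alpha
  res0 <- replication_test_presence(null$presence, null$metadata,
                                    n_runs = 10, seed = 32)
  expect_lt(mean(res0$results$replicable), 0.2)
})

test_that("rank AUC agrees with pROC and stability analysis behaves", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    sc <- c(rnorm(50, 1), rnorm(60))
    lb <- rep(c(TRUE, FALSE), c(50, 60))
    got <- dhsatlas:::rank_auc(sc, lb)
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-12)
  })
  expect_true(is.na(dhsatlas:::rank_auc(1:5, rep(TRUE, 5))))
})

test_that("stability analysis AUC approaches 1 as runs accumulate", {
  null <- simulate_null_presence(800, n_cell_types = 40, n_replicates = 3,
                                 seed = 41)
  # mix of concordant and null clusters so labels are non-degenerate
  P <- null$presence
  cts <- unique(null$metadata$cell_type)
  for (ct in cts) {
    ids <- null$metadata$sample_id[null$metadata$cell_type == ct]
    P[1:200, ids[2]] <- P[1:200, ids[1]]
  }
  md <- null$metadata
  cl <- structure(list(
    clusters = data.table::data.table(cluster_id = seq_len(nrow(P))),
    members = data.table::data.table()), class = "dhs_clusters")
  # use the presence-matrix variant directly
  pairings <- draw_pairings(md, n_runs = 12, seed = 42)
  stats <- dhsatlas:::run_statistics(P, pairings)
  ref <- combined_test(stats)$replicable
  expect_true(any(ref) && !all(ref))
  auc_small <- dhsatlas:::rank_auc(-combined_test(stats[, 1, drop = FALSE])$p_value, ref)
  auc_big <- dhsatlas:::rank_auc(-combined_test(stats[, 1:11])$p_value, ref)
  expect_gt(auc_big, auc_small)
  expect_gt(auc_big, 0.95)
})

test_that("stability analysis reports undefined AUC for one-class labels", {
  # two cell types only: even perfect concordance cannot reach p <= 0.05,
  # so the reference labels are all negative and the AUC is undefined
  md <- data.table::data.table(
    sample_id = c("a1", "a2", "b1", "b2"),
    cell_type = c("A", "A", "B", "B"))
  pk <- rbind(peaks_dt("chr1", rep(100, 4), rep(500, 4), sample_id = md$sample_id),
              peaks_dt("chr1", 5000, 5400, sample_id = "a1"))
  cl <- cluster_peaks(pk)
  expect_warning(st <- stability_analysis(cl, md, max_runs = 5, seed = 9),
                 "one class")
  expect_true(all(is.na(st$auc)))
  expect_equal(st$n_runs, 1:4)
})
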