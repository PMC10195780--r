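test_that("interval similarity is the bp-level Jaccard index", {
  expect_equal(interval_similarity("chr1", 0, 100, "chr1", 0, 100), 1.0)
  expect_equal(interval_similarity("chr1", 0, 100, "chr1", 200, 300), 0.0)
  expect_equal(interval_similarity("chr1", 0, 100, "chr2", 0, 100), 0.0)
  expect_equal(interval_similarity("chr1", 0, 100, "chr1", 50, 150), 1 / 3)
  # symmetric, and adjacent half-open intervals do not overlap
  expect_equal(interval_similarity("chr1", 50, 150, "chr1", 0, 100), 1 / 3)
  expect_equal(interval_similarity("chr1", 0, 100, "chr1", 100, 200), 0.0)
  expect_error(interval_similarity("chr1", 100, 100, "chr1", 0, 50),
               "invalid interval")
})

test_that("overlap graph has one weighted edge per overlapping pair", {
  # non-overlapping peaks: isolated nodes
  g0 <- build_overlap_graph(peaks_dt("chr1", c(0, 200, 400), c(100, 300, 500)))
  expect_equal(nrow(g0$edges), 0L)
  # three mutually overlapping peaks: a triangle
  g3 <- build_overlap_graph(peaks_dt("chr1", c(0, 50, 80), c(200, 250, 300)))
  expect_equal(nrow(g3$edges), 3L)
  expect_true(all(g3$edges$w > 0 & g3$edges$w <= 1))
  expect_error(build_overlap_graph(peaks_dt(c("chr1", "chr2"), c(0, 0),
                                            c(10, 10))),
               "single chromosome")
})

test_that("sweep-built edges match the brute-force all-pairs oracle", {
  withr::with_seed(42, {
    pk <- random_chrom_peaks(200)
    g <- build_overlap_graph(pk)
    # oracle: O(n^2) scan over the same (canonically sorted) peaks
    p <- g$peaks
    brute <- 0L
    for (i in seq_len(nrow(p) - 1)) for (j in seq(i + 1, nrow(p))) {
      w <- interval_similarity(p$chrom[i], p$start[i], p$end[i],
                               p$chrom[j], p$start[j], p$end[j])
      if (w > 0) brute <- brute + 1L
    }
    expect_equal(nrow(g$edges), brute)
  })
})

test_that("connected components match a hand-rolled union-find oracle", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      pk <- random_chrom_peaks(80)
      g <- build_overlap_graph(pk)
      memb <- graph_components(g)
      # union-find oracle
      parent <- seq_len(nrow(g$peaks))
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (k in seq_len(nrow(g$edges))) {
        ri <- find(g$edges$i[k]); rj <- find(g$edges$j[k])
        if (ri != rj) parent[ri] <- rj
      }
      roots <- vapply(seq_along(parent), find, 1L)
      expect_equal(length(unique(memb)), length(unique(roots)))
      # same partition up to relabeling
      split_a <- split(seq_along(memb), memb)
      split_b <- split(seq_along(roots), roots)
      expect_setequal(unname(vapply(split_a, paste, "", collapse = ",")),
                      unname(vapply(split_b, paste, "", collapse = ",")))
    }
  })
  expect_equal(graph_components(build_overlap_graph(peaks_dt(character(0),
                                                             integer(0),
                                                             integer(0)))),
               integer(0))
})

test_that("MCL separates the bridged two-clique fixture like the reference", {
  A <- bridged_cliques()
  got <- mcl_cluster(A)
  expect_equal(got, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(got, reference_mcl(bridged_cliques()))
})

test_that("MCL merges a strongly linked pair and keeps singletons", {
  expect_equal(mcl_cluster(matrix(c(0, 1, 1, 0), 2)), c(1L, 1L))
  expect_equal(mcl_cluster(matrix(0, 1, 1)), 1L)
  # two-node fast path agrees with the dense iteration across weights
  for (w in c(0.01, 0.05, 0.15, 0.25, 0.4, 0.7, 1.0)) {
    a2 <- matrix(c(0, w, w, 0), 2)
    expect_equal(mcl_cluster(a2),
                 dhsatlas:::mcl_partition_dense(a2, mcl_params()),
                 info = paste("w =", w))
  }
})

test_that("mcl_params validates its arguments", {
  expect_error(mcl_params(inflation = 1), "inflation")
  expect_error(mcl_params(expansion = 1), "expansion")
  expect_error(mcl_params(prune_threshold = 0), "tolerances")
})

test_that("cluster_peaks aligns identical stacks and separates gapped ones", {
  # the same peak in five samples, nothing else nearby -> one cluster
  stack <- peaks_dt("chr1", rep(1000, 5), rep(1400, 5),
                    sample_id = paste0("s", 1:5))
  cl <- cluster_peaks(stack)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n_samples, 5L)
  expect_equal(cl$clusters[, .(start, end)],
               data.table::data.table(start = 1000L, end = 1400L))
  # two stacks separated by a gap -> two clusters
  two <- rbind(stack, peaks_dt("chr1", rep(5000, 4), rep(5300, 4),
                               sample_id = paste0("s", 1:4)))
  cl2 <- cluster_peaks(two)
  expect_equal(nrow(cl2$clusters), 2L)
  expect_equal(sort(cl2$clusters$n_peaks), c(4L, 5L))
})

test_that("clustering partitions the peaks and ignores input order", {
  withr::with_seed(99, {
    pk <- rbind(random_chrom_peaks(150, chrom = "chr1"),
                random_chrom_peaks(80, chrom = "chr2"))
    cl <- cluster_peaks(pk)
    # conservation: every peak in exactly one cluster
    expect_equal(nrow(cl$members), nrow(pk))
    expect_equal(sum(cl$clusters$n_peaks), nrow(pk))
    # locality: cluster members stay within the span on one chromosome
    bad <- cl$members[, .(ok = all(start >= min(start) & end <= max(end)) &&
                            data.table::uniqueN(chrom) == 1L),
                      by = cluster_id]
    expect_true(all(bad$ok))
    # permutation invariance: shuffled input gives the identical partition
    shuf <- pk[sample.int(nrow(pk))]
    cl_b <- cluster_peaks(shuf)
    key_a <- cl$members[order(chrom, start, end, sample_id),
                        .(chrom, start, end, sample_id, cluster_id)]
    key_b <- cl_b$members[order(chrom, start, end, sample_id),
                          .(chrom, start, end, sample_id, cluster_id)]
    expect_equal(key_a$cluster_id, key_b$cluster_id)
  })
})

test_that("re-clustering well-separated cluster spans returns singletons", {
  spans <- peaks_dt("chr1", seq(0, 9000, by = 1000),
                    seq(400, 9400, by = 1000))
  cl <- cluster_peaks(spans)
  expect_equal(nrow(cl$clusters), 10L)
  expect_true(all(cl$clusters$n_peaks == 1L))
})

test_that("empty input yields an empty result with a warning", {
  expect_warning(cl <- cluster_peaks(peaks_dt(character(0), integer(0),
                                              integer(0))),
                 "no peaks")
  expect_equal(nrow(cl$clusters), 0L)
})

test_that("lower inflation never gives a finer partition of a fixture graph", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      pk <- random_chrom_peaks(60)
      coarse <- cluster_peaks(pk, mcl_params(inflation = 1.4))
      fine <- cluster_peaks(pk, mcl_params(inflation = 2.0))
      expect_lte(nrow(coarse$clusters), nrow(fine$clusters))
    }
  })
})
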