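# Cross-sample peak alignment. Peaks from all samples on one chromosome are
# nodes of a weighted graph whose edges carry the interval Jaccard similarity
# (intersection length / union length) of overlapping peak pairs. The graph
# is decomposed into connected components and each component is partitioned
# with Markov clustering (MCL). Every input peak ends up in exactly one DHS
# cluster; the cluster span is the union extent of its members.

#' MCL parameter set
#'
#' The classical MCL defaults: expansion by matrix squaring, inflation 2.0,
#' unit self-loops, pruning of tiny entries for sparsity.
#'
#' @param inflation entrywise-power inflation exponent (> 1). Larger values
#'   give finer partitions.
#' @param expansion integer matrix-power expansion exponent (>= 2).
#' @param prune_threshold entries below this are dropped after each iteration.
#' @param convergence_tol stop when the largest entrywise change falls below
#'   this.
#' @param max_iterations iteration cap; non-convergence yields a warning and
#'   the current partition.
#' @param self_loop_weight weight of the self-loop added to every node.
#' @return list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2.0, expansion = 2L,
                       prune_threshold = 1e-5, convergence_tol = 1e-6,
                       max_iterations = 100L, self_loop_weight = 1.0) {
  abort_if(inflation <= 1, "inflation must be > 1")
  abort_if(expansion < 2 || expansion != floor(expansion),
           "expansion must be an integer >= 2")
  abort_if(prune_threshold <= 0 || convergence_tol <= 0,
           "tolerances must be > 0")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 self_loop_weight = self_loop_weight),
            class = "mcl_params")
}

#' Jaccard similarity of two genomic intervals
#'
#' Length of intersection divided by length of union, in bp, under 0-based
#' half-open arithmetic. Intervals on different chromosomes, or disjoint
#' intervals, have similarity 0. Vectorized over its arguments.
#'
#' @param chrom_a,start_a,end_a first interval(s).
#' @param chrom_b,start_b,end_b second interval(s).
#' @return numeric in \[0, 1\].
#' @examples
#' interval_similarity("chr1", 0, 100, "chr1", 50, 150) # 1/3
#' @export
interval_similarity <- function(chrom_a, start_a, end_a,
                                chrom_b, start_b, end_b) {
  abort_if(any(start_a >= end_a) || any(start_b >= end_b),
           "invalid interval: start must be < end")
  inter <- pmin(end_a, end_b) - pmax(start_a, start_b)
  inter <- pmax(inter, 0)
  uni <- (end_a - start_a) + (end_b - start_b) - inter
  out <- inter / uni
  out[normalize_chrom(chrom_a) != normalize_chrom(chrom_b)] <- 0
  out
}

#' Build the interval-overlap similarity graph for one chromosome
#'
#' Overlapping peak pairs are found with an interval-tree query
#' ([IRanges::findOverlaps()]), never by all-pairs comparison, and weighted
#' by [interval_similarity()]. Every node carries a self-loop.
#'
#' @param peaks `data.table` of peaks on a single chromosome (columns
#'   `chrom`, `start`, `end`; any others are carried along).
#' @param self_loop_weight self-loop weight added to every node.
#' @return list of class `peak_graph`: `peaks` (canonically sorted),
#'   `edges` (`data.table` of node indices `i < j` and weight `w`),
#'   `self_loop_weight`.
#' @export
build_overlap_graph <- function(peaks, self_loop_weight = 1.0) {
  peaks <- data.table::as.data.table(peaks)
  abort_if(length(unique(peaks$chrom)) > 1L,
           "build_overlap_graph expects peaks from a single chromosome")
  # canonical node order makes the clustering invariant to input order
  ord <- do.call(order, unname(as.list(
    peaks[, intersect(c("start", "end", "sample_id", "neglog10_p"),
                      names(peaks)), with = FALSE])))
  peaks <- peaks[ord]
  if (nrow(peaks) == 0L) {
    edges <- data.table::data.table(i = integer(), j = integer(), w = numeric())
  } else {
    ir <- IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
    hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    qi <- S4Vectors::queryHits(hits)
    sj <- S4Vectors::subjectHits(hits)
    w <- interval_similarity(peaks$chrom[qi], peaks$start[qi], peaks$end[qi],
                             peaks$chrom[sj], peaks$start[sj], peaks$end[sj])
    edges <- data.table::data.table(i = pmin(qi, sj), j = pmax(qi, sj), w = w)
    data.table::setorder(edges, i, j)
  }
  structure(list(peaks = peaks, edges = edges,
                 self_loop_weight = self_loop_weight),
            class = "peak_graph")
}

#' Connected components of a peak graph
#'
#' @param graph a `peak_graph`.
#' @return integer membership vector (component id per node), components
#'   numbered in order of their smallest node.
#' @export
graph_components <- function(graph) {
  n <- nrow(graph$peaks)
  if (n == 0L) return(integer(0))
  g <- igraph::make_graph(as.vector(rbind(graph$edges$i, graph$edges$j)),
                          n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber by first occurrence so the labels are canonical
  as.integer(factor(memb, levels = unique(memb)))
}

# Core MCL iteration on a column-stochastic matrix built from a symmetric
# similarity matrix with self-loops. Dense path; components are small after
# the connected-component decomposition.
mcl_partition_dense <- function(adj, params) {
  n <- nrow(adj)
  M <- adj
  diag(M) <- diag(M) + params$self_loop_weight
  M <- sweep(M, 2L, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    E <- M
    for (e in seq_len(params$expansion - 1L)) E <- E %*% M
    E <- E ^ params$inflation
    E[E < params$prune_threshold] <- 0
    cs <- colSums(E)
    cs[cs == 0] <- 1
    E <- sweep(E, 2L, cs, "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iterations,
            " iterations; returning current partition")
  mcl_read_clusters(M)
}

# Interpret a converged MCL matrix: attractors are rows with positive
# diagonal; attractors that attract one another form one attractor system;
# every node goes to the system with the largest total attraction weight,
# ties to the smallest system index.
mcl_read_clusters <- function(M) {
  n <- nrow(M)
  attract <- which(Matrix::diag(M) > 0)
  if (length(attract) == 0L) {
    # degenerate (non-converged cyclic state): fall back to components of
    # the positive pattern
    g <- igraph::graph_from_adjacency_matrix(
      (as.matrix(M) + t(as.matrix(M))) > 0, mode = "undirected")
    memb <- igraph::components(g)$membership
    return(as.integer(factor(memb, levels = unique(memb))))
  }
  Ma <- as.matrix(M[attract, , drop = FALSE])
  # union attractors that appear in each other's rows
  cross <- (Ma[, attract, drop = FALSE] > 0) | t(Ma[, attract, drop = FALSE] > 0)
  g <- igraph::graph_from_adjacency_matrix(cross, mode = "undirected")
  sys_of_attract <- igraph::components(g)$membership
  sys_of_attract <- as.integer(factor(sys_of_attract,
                                      levels = unique(sys_of_attract)))
  n_sys <- max(sys_of_attract)
  # total attraction of each node to each system
  W <- matrix(0, n_sys, n)
  for (s in seq_len(n_sys)) {
    rows <- which(sys_of_attract == s)
    W[s, ] <- colSums(Ma[rows, , drop = FALSE])
  }
  memb <- apply(W, 2L, which.max) # which.max takes the smallest index on ties
  # nodes with no attraction mass (fully pruned columns): own singleton
  none <- colSums(W) == 0
  if (any(none)) memb[none] <- n_sys + seq_len(sum(none))
  as.integer(factor(memb, levels = unique(memb)))
}

# Closed fast path for 2-node components: the column-stochastic matrix stays
# symmetric, so the state is one number (the off-diagonal mass q) and the
# expansion/inflation updates reduce to scalar recurrences.
mcl_two_node <- function(w, params) {
  q <- w / (w + params$self_loop_weight)
  for (it in seq_len(params$max_iterations)) {
    # expansion: M^e for M = [[1-q, q], [q, 1-q]]; track off-diagonal mass
    q1 <- q
    qq <- q
    for (e in seq_len(params$expansion - 1L)) qq <- (1 - qq) * q1 + qq * (1 - q1)
    # inflation with pruning and column renormalization
    qi <- qq ^ params$inflation
    pi_ <- (1 - qq) ^ params$inflation
    if (qi < params$prune_threshold) qi <- 0
    if (pi_ < params$prune_threshold) pi_ <- 0
    qn <- if (qi + pi_ == 0) qq else qi / (qi + pi_)
    delta <- abs(qn - q)
    q <- qn
    if (delta < params$convergence_tol) break
  }
  if (q > 0.25) c(1L, 1L) else c(1L, 2L)
}

#' Markov clustering of one connected component
#'
#' Builds the column-stochastic transition matrix from the similarity weights
#' plus self-loops and alternates expansion (matrix power), inflation
#' (entrywise power with column renormalization) and pruning until the
#' largest entrywise change drops below `convergence_tol`. Clusters are read
#' off as attractor systems; nodes attracted to several systems are assigned
#' to the one with the largest attraction weight (ties to the smallest
#' cluster index), so the result is a hard partition.
#'
#' @param graph a `peak_graph` (assumed connected), or a symmetric numeric
#'   similarity matrix (zero diagonal; self-loops are added internally).
#' @param params an [mcl_params()] list.
#' @return integer cluster membership per node, numbered by first occurrence.
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  if (inherits(graph, "peak_graph")) {
    n <- nrow(graph$peaks)
    adj <- matrix(0, n, n)
    if (nrow(graph$edges) > 0) {
      adj[cbind(graph$edges$i, graph$edges$j)] <- graph$edges$w
      adj[cbind(graph$edges$j, graph$edges$i)] <- graph$edges$w
    }
    params$self_loop_weight <- graph$self_loop_weight
  } else {
    adj <- as.matrix(graph)
    abort_if(!isSymmetric(unname(adj)), "similarity matrix must be symmetric")
    n <- nrow(adj)
  }
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  if (n == 2L) return(mcl_two_node(adj[1, 2], params))
  mcl_partition_dense(adj, params)
}

#' Cluster peaks across samples into DHS clusters
#'
#' Runs the full alignment: per-chromosome overlap graphs, connected
#' components, MCL per component (singleton components pass through without
#' MCL). Deterministic given the peaks and parameters, and invariant to the
#' input row order.
#'
#' @param peaks `data.table` of peaks from all samples (columns `chrom`,
#'   `start`, `end`, `sample_id`, `neglog10_p`).
#' @param params an [mcl_params()] list.
#' @return object of class `dhs_clusters`: `clusters` (`data.table` of
#'   `cluster_id`, `chrom`, `start`, `end`, `n_peaks`, `n_samples`) and
#'   `members` (`data.table` of peaks with their `cluster_id`).
#' @export
cluster_peaks <- function(peaks, params = mcl_params()) {
  peaks <- data.table::as.data.table(peaks)
  if (nrow(peaks) == 0L) {
    warning("no peaks to cluster")
    return(structure(list(
      clusters = data.table::data.table(cluster_id = integer(),
                                        chrom = character(), start = integer(),
                                        end = integer(), n_peaks = integer(),
                                        n_samples = integer()),
      members = data.table::data.table()), class = "dhs_clusters"))
  }
  member_list <- list()
  for (chr in sort(unique(peaks$chrom))) {
    graph <- build_overlap_graph(peaks[peaks$chrom == chr],
                                 self_loop_weight = params$self_loop_weight)
    comp <- graph_components(graph)
    labels <- integer(length(comp))
    next_id <- 0L
    for (cid in seq_len(max(comp))) {
      nodes <- which(comp == cid)
      if (length(nodes) == 1L) {
        labels[nodes] <- next_id + 1L
        next_id <- next_id + 1L
        next
      }
      sub_edges <- graph$edges[graph$edges$i %in% nodes &
                                 graph$edges$j %in% nodes]
      remap <- integer(nrow(graph$peaks))
      remap[nodes] <- seq_along(nodes)
      sub <- structure(list(
        peaks = graph$peaks[nodes],
        edges = data.table::data.table(i = remap[sub_edges$i],
                                       j = remap[sub_edges$j],
                                       w = sub_edges$w),
        self_loop_weight = graph$self_loop_weight), class = "peak_graph")
      part <- mcl_cluster(sub, params)
      labels[nodes] <- next_id + part
      next_id <- next_id + max(part)
    }
    m <- data.table::copy(graph$peaks)
    m[, `:=`(.chr_label = labels)]
    member_list[[chr]] <- m
  }
  members <- data.table::rbindlist(member_list, idcol = ".chr")
  # global cluster ids ordered by chromosome then span start
  key <- members[, list(start = min(start)),
                 by = c(".chr", ".chr_label")]
  data.table::setorder(key, .chr, start, .chr_label)
  key[, cluster_id := seq_len(.N)]
  members <- merge(members, key[, c(".chr", ".chr_label", "cluster_id")],
                   by = c(".chr", ".chr_label"), sort = FALSE)
  members[, c(".chr", ".chr_label") := NULL]
  clusters <- members[, list(
    chrom = chrom[1L], start = min(start), end = max(end),
    n_peaks = .N, n_samples = data.table::uniqueN(sample_id)),
    by = "cluster_id"]
  data.table::setorder(clusters, cluster_id)
  data.table::setorder(members, cluster_id, start, end, sample_id)
  structure(list(clusters = clusters[], members = members[]),
            class = "dhs_clusters")
}

#' @export
print.dhs_clusters <- function(x, ...) {
  cat("<dhs_clusters> ", nrow(x$clusters), " clusters from ",
      nrow(x$members), " peaks across ",
      data.table::uniqueN(x$members$sample_id), " samples\n", sep = "")
  invisible(x)
}

#' Export the peak-to-cluster membership table as TSV
#'
#' @param clusters a `dhs_clusters` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_membership <- function(clusters, path) {
  stopifnot(inherits(clusters, "dhs_clusters"))
  data.table::fwrite(clusters$members, path, sep = "\t")
  invisible(path)
}
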