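# Proportional-cost thresholding and the graph-metric suite on binary,
# undirected, zero-diagonal adjacency matrices.  Shortest-path kernels are
# compiled (BFS); betweenness and local clustering are delegated to igraph.

#' Threshold a connectivity matrix at a fixed cost
#'
#' Retains the strongest entries of the (symmetric) connectivity matrix so
#' that the resulting binary graph has exactly round(cost * N(N-1)/2) edges.
#' Fixing the cost equates edge counts across subjects, which is what makes
#' graph metrics comparable across individuals and ages.  Ties are broken
#' deterministically by (value descending, row-major pair index ascending).
#'
#' @param C Symmetric numeric matrix (e.g. a \code{connectivity_matrix}).
#' @param cost Proportion of retained edges, in (0, 1].
#' @return An \code{adjacency_matrix}: binary symmetric matrix with zero
#'   diagonal and attributes \code{cost} and \code{band}.
#' @export
threshold_proportional <- function(C, cost) {
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0 || cost > 1)
    stop("threshold_proportional: cost must be in (0, 1]")
  C <- unclass(as.matrix(C))
  n <- nrow(C)
  if (n != ncol(C)) stop("threshold_proportional: matrix not square")
  if (max(abs(C - t(C))) > 1e-8)
    stop("threshold_proportional: matrix not symmetric")
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  w <- C[cbind(ii, jj)]
  m <- floor(cost * n * (n - 1) / 2 + 0.5)   # round half up
  A <- matrix(0, n, n)
  if (m > 0L) {
    keep <- order(-w, (ii - 1L) * n + jj)[seq_len(min(m, length(w)))]
    A[cbind(ii[keep], jj[keep])] <- 1
    A <- A + t(A)
  }
  dimnames(A) <- dimnames(C)
  structure(A, class = c("adjacency_matrix", "matrix", "array"),
            cost = cost, band = attr(C, "band"))
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("<adjacency_matrix> %d nodes, %d edges (cost %.3g)\n",
              nrow(x), sum(x) / 2, attr(x, "cost")))
  invisible(x)
}

as_adj <- function(A) {
  A <- unclass(as.matrix(A))
  storage.mode(A) <- "double"
  A
}

as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(as_adj(A), mode = "undirected",
                                      diag = FALSE)
}

#' Shortest-path (hop-count) distance matrix
#'
#' d_ij is the minimum number of edges between nodes i and j (equivalently
#' the smallest power n with (A^n)_ij nonzero); unreachable pairs are Inf
#' and d_ii = 0.
#'
#' @param A Binary adjacency matrix.
#' @return Numeric N x N distance matrix.
#' @export
graph_distances <- function(A) {
  cpp_bfs_distances(as_adj(A))
}

#' Average shortest path length
#'
#' Mean of d_ij over ordered pairs.  The printed definition assumes a
#' connected graph; for disconnected graphs the mean is taken over reachable
#' pairs only and the reachable-pair fraction is reported alongside.
#'
#' @param A Binary adjacency matrix.
#' @return Scalar L (NA if no pair is reachable) with attribute
#'   \code{reachable_fraction}.
#' @export
path_length <- function(A) {
  d <- graph_distances(A)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  L <- if (any(reach)) mean(off[reach]) else NA_real_
  structure(L, reachable_fraction = mean(reach))
}

#' Node degree
#'
#' Number of edges incident on each node (row sums of A); the basic hubness
#' measure.
#'
#' @param A Binary adjacency matrix.
#' @return Integer-valued numeric vector of length N.
#' @export
node_degree <- function(A) {
  rowSums(as_adj(A))
}

#' Local clustering coefficient
#'
#' Per node, the density of its neighbourhood subgraph: the fraction of
#' possible edges among its neighbours that exist, 2|{e_jk}| / (k_i (k_i-1));
#' zero for nodes with fewer than two neighbours.
#'
#' @param A Binary adjacency matrix.
#' @return Numeric vector in [0, 1] of length N.
#' @export
clustering_coef <- function(A) {
  out <- igraph::transitivity(as_igraph(A), type = "local", isolates = "zero")
  out[is.na(out)] <- 0
  out
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance, with
#' 1/Inf taken as 0; a proxy for the network's capacity for integrated,
#' long-range communication.
#'
#' @param A Binary adjacency matrix.
#' @return Scalar in [0, 1].
#' @export
global_efficiency <- function(A) {
  cpp_global_efficiency(as_adj(A))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced on its
#' neighbours (how efficiently they can communicate if the node is removed);
#' zero where the degree is below 2.  The network value is the mean over
#' nodes, a proxy for clustered, segregated processing.
#'
#' @param A Binary adjacency matrix.
#' @param per_node If TRUE return the per-node vector E(G_i).
#' @return Scalar mean local efficiency, or the per-node vector.
#' @export
local_efficiency <- function(A, per_node = FALSE) {
  v <- cpp_local_efficiency(as_adj(A))
  if (per_node) v else mean(v)
}

#' Betweenness centrality
#'
#' b_i = sum over unordered pairs (m, n), endpoints excluded, of the
#' fraction of shortest m-n paths passing through i.  Unnormalized, matching
#' the printed definition; high values mark hubs.
#'
#' @param A Binary adjacency matrix.
#' @return Non-negative numeric vector of length N.
#' @export
betweenness_centrality <- function(A) {
  as.vector(igraph::betweenness(as_igraph(A), directed = FALSE,
                                normalized = FALSE))
}

#' All graph metrics of one adjacency matrix
#'
#' @param A Binary adjacency matrix.
#' @return A \code{graph_metric_set}: L (+ reachable fraction), degree,
#'   clustering, global and local efficiency (mean and per node), and
#'   betweenness.
#' @export
graph_metrics <- function(A) {
  L <- path_length(A)
  eloc_i <- local_efficiency(A, per_node = TRUE)
  structure(list(L = as.numeric(L),
                 reachable_fraction = attr(L, "reachable_fraction"),
                 degree = node_degree(A),
                 clustering = clustering_coef(A),
                 global_efficiency = global_efficiency(A),
                 local_efficiency = mean(eloc_i),
                 local_efficiency_node = eloc_i,
                 betweenness = betweenness_centrality(A),
                 cost = attr(A, "cost")),
            class = "graph_metric_set")
}

#' @export
print.graph_metric_set <- function(x, ...) {
  cat("<graph_metric_set>\n")
  cat(sprintf("  nodes: %d   mean degree: %.2f\n",
              length(x$degree), mean(x$degree)))
  cat(sprintf("  L: %.3f (reachable %.0f%%)   C: %.3f\n",
              x$L, 100 * x$reachable_fraction, mean(x$clustering)))
  cat(sprintf("  Eglob: %.3f   Eloc: %.3f   max betweenness: %.1f\n",
              x$global_efficiency, x$local_efficiency, max(x$betweenness)))
  invisible(x)
}

#' Default proportional-cost grid
#'
#' Costs from 5\% to 30\% in 5\% increments, the standard comparison range
#' when no single cost can be justified a priori.
#'
#' @return Numeric vector of costs.
#' @export
default_costs <- function() seq(0.05, 0.30, by = 0.05)

metric_fun <- function(name) {
  switch(name,
         global_efficiency = global_efficiency,
         local_efficiency  = function(A) local_efficiency(A),
         path_length       = function(A) as.numeric(path_length(A)),
         clustering        = function(A) mean(clustering_coef(A)),
         stop("unknown metric: ", name))
}

#' Subject x cell matrix of graph metrics over a band/cost/metric grid
#'
#' Thresholds each subject's per-band connectivity matrix at every cost and
#' evaluates the requested scalar network metrics.  The returned matrix
#' (subjects x cells, cell names "band|cost|metric") is the input shape the
#' maximum-statistics correction expects.
#'
#' @param conn Named list: band -> list of per-subject connectivity matrices.
#' @param costs Cost grid; default \code{\link{default_costs}}.
#' @param metrics Character vector of metric names (any of
#'   "global_efficiency", "local_efficiency", "path_length", "clustering").
#' @return Numeric matrix with one row per subject and one column per
#'   band x cost x metric cell.
#' @export
metric_grid <- function(conn, costs = default_costs(),
                        metrics = c("global_efficiency", "local_efficiency")) {
  stopifnot(is.list(conn), length(conn) > 0)
  n_sub <- length(conn[[1L]])
  cells <- expand.grid(metric = metrics, cost = costs, band = names(conn),
                       stringsAsFactors = FALSE)
  out <- matrix(NA_real_, nrow = n_sub, ncol = nrow(cells))
  colnames(out) <- sprintf("%s|%g|%s", cells$band, cells$cost, cells$metric)
  for (b in names(conn)) {
    if (length(conn[[b]]) != n_sub)
      stop("metric_grid: unequal subject counts across bands")
    for (s in seq_len(n_sub)) {
      C <- conn[[b]][[s]]
      for (co in costs) {
        A <- threshold_proportional(C, co)
        for (m in metrics) {
          col <- sprintf("%s|%g|%s", b, co, m)
          out[s, col] <- metric_fun(m)(A)
        }
      }
    }
  }
  out
}
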