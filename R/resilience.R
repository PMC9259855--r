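# Network resilience: targeted and random node-removal attacks with
# normalized global efficiency, score-ranked removal from external per-node
# score maps, and the per-removal age-correlation scan with
# maximum-statistics correction.

#' Rank nodes for targeted removal
#'
#' Orders nodes by descending score (degree for classic targeted attacks,
#' or an external per-node score such as a meta-analytic z) with ties broken
#' by ascending node id, so the removal order is deterministic.
#'
#' @param scores Numeric vector of per-node scores, or a data.frame with
#'   columns node_id and score (a node score map).
#' @param top_k How many nodes to return; default all.
#' @return Integer vector of node indices (or the node_id values for a
#'   score-map data.frame), length top_k, descending score.
#' @export
rank_nodes <- function(scores, top_k = NULL) {
  if (is.data.frame(scores)) {
    if (!all(c("node_id", "score") %in% names(scores)))
      stop("rank_nodes: score map needs columns node_id and score")
    ids <- scores$node_id
    v <- scores$score
  } else {
    v <- as.numeric(scores)
    ids <- seq_along(v)
  }
  if (anyNA(v))
    stop("rank_nodes: missing scores for node(s) ",
         paste(ids[is.na(v)], collapse = ", "))
  if (is.null(top_k)) top_k <- length(v)
  if (top_k > length(v)) stop("rank_nodes: top_k exceeds node count")
  ids[order(-v, ids)][seq_len(top_k)]
}

#' Targeted node-removal attack
#'
#' Removes the listed nodes one at a time (node and incident edges deleted,
#' remaining-node convention) and recomputes global efficiency after each
#' removal, normalized by the intact graph's efficiency.  r_0 = 1 by
#' construction; a graph reduced below two nodes has efficiency 0.
#'
#' @param A Binary adjacency matrix with at least one edge.
#' @param order Integer vector of node indices to remove, no duplicates.
#' @return A \code{resilience_curve}: \code{r} (normalized efficiencies,
#'   length k+1 including r_0), \code{order}, \code{e0} (original Eglob).
#' @export
attack <- function(A, order) {
  A <- as_adj(A)
  n <- nrow(A)
  order <- as.integer(order)
  if (anyDuplicated(order)) stop("attack: duplicate nodes in removal order")
  if (any(order < 1L | order > n)) stop("attack: node index out of range")
  e0 <- cpp_global_efficiency(A)
  if (e0 == 0) stop("attack: graph has no edges (Eglob = 0)")
  r <- numeric(length(order) + 1L)
  r[1L] <- 1
  alive <- rep(TRUE, n)
  for (k in seq_along(order)) {
    alive[order[k]] <- FALSE
    sub <- A[alive, alive, drop = FALSE]
    ek <- if (sum(alive) < 2L) 0 else cpp_global_efficiency(sub)
    r[k + 1L] <- ek / e0
  }
  structure(list(r = r, order = order, e0 = e0),
            class = "resilience_curve")
}

#' @export
print.resilience_curve <- function(x, ...) {
  cat(sprintf("<resilience_curve> %d removal(s), r_final = %.3f\n",
              length(x$order), x$r[length(x$r)]))
  invisible(x)
}

#' @export
plot.resilience_curve <- function(x, xlab = "nodes removed",
                                  ylab = "normalized global efficiency",
                                  ...) {
  graphics::plot(seq_along(x$r) - 1L, x$r, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Random-attack resilience curve
#'
#' Mean normalized-efficiency curve over uniformly random removal orders,
#' the baseline that targeted (hub-first) attacks are compared against.
#'
#' @param A Binary adjacency matrix.
#' @param n_remove Number of nodes removed per replicate.
#' @param n_reps Number of random orders averaged; default 100.
#' @param seed Integer seed.
#' @return A \code{resilience_curve} whose \code{r} is the mean curve, with
#'   \code{n_reps} recorded.
#' @export
random_attack <- function(A, n_remove, n_reps = 100L, seed = 1L) {
  A <- as_adj(A)
  if (n_remove > nrow(A)) stop("random_attack: n_remove exceeds node count")
  set.seed(seed)
  acc <- numeric(n_remove + 1L)
  e0 <- cpp_global_efficiency(A)
  for (rep in seq_len(n_reps)) {
    ord <- sample.int(nrow(A), n_remove)
    acc <- acc + attack(A, ord)$r
  }
  structure(list(r = acc / n_reps, order = NA_integer_, e0 = e0,
                 n_reps = n_reps),
            class = "resilience_curve")
}

#' Build a node score map from vertex-level scores
#'
#' Averages per-vertex scores (e.g. meta-analytic association z-scores)
#' within each node's vertices, producing the per-node score used for
#' score-ranked removal.
#'
#' @param vertex_scores data.frame(vertex_id, z).
#' @param membership data.frame(vertex_id, node_id).
#' @param term Label attached to the map.
#' @return data.frame(node_id, score, term), one row per node.
#' @export
node_scores_from_vertices <- function(vertex_scores, membership,
                                      term = "term") {
  if (!all(c("vertex_id", "z") %in% names(vertex_scores)))
    stop("node_scores_from_vertices: vertex_scores needs vertex_id, z")
  if (!all(c("vertex_id", "node_id") %in% names(membership)))
    stop("node_scores_from_vertices: membership needs vertex_id, node_id")
  merged <- merge(membership, vertex_scores, by = "vertex_id")
  agg <- stats::aggregate(z ~ node_id, data = merged, FUN = mean)
  data.frame(node_id = agg$node_id, score = agg$z, term = term,
             stringsAsFactors = FALSE)
}

#' Per-removal age-correlation scan of resilience
#'
#' For a fixed, score-derived removal order (identical for every subject),
#' removes up to \code{max_remove} nodes from each subject's graph,
#' recomputes each subject's global efficiency normalized by their own
#' intact efficiency after every removal, and correlates the normalized
#' efficiency at each removal count with age (Spearman).  P-values are
#' corrected by maximum statistics over the full declared comparison space:
#' bands x removals x terms, with one age shuffle per permutation reused
#' across all cells.  The removal index maximizing |rho| per band and term
#' (the "snapshot") is reported alongside the full curve.
#'
#' @param adjacency Per-subject adjacency matrices: either a list (single
#'   band) or a named list band -> list of matrices (same node order for
#'   every subject).
#' @param ages Numeric vector, one age per subject (>= 3 subjects).
#' @param orders Removal order(s): an integer vector (single term) or a
#'   named list term -> integer vector.
#' @param max_remove Removals scanned; default 90.
#' @param n_p Permutations for the correction; default 10000.
#' @param seed Integer seed.
#' @return A \code{resilience_scan}: data.frame \code{table} (band, term,
#'   k, node_removed, rho, p_raw, p_c), \code{snapshot} (per band x term),
#'   and the \code{corrected_correlation} object.
#' @export
age_resilience_scan <- function(adjacency, ages, orders, max_remove = 90L,
                                n_p = 10000L, seed = 1L) {
  if (!is.list(adjacency[[1L]])) adjacency <- list(band = adjacency)
  if (!is.list(orders)) orders <- list(term = orders)
  n_sub <- length(adjacency[[1L]])
  if (n_sub < 3L) stop("age_resilience_scan: need at least 3 subjects")
  if (length(ages) != n_sub)
    stop("age_resilience_scan: ages and subjects mismatch")
  for (term in names(orders)) {
    ord <- orders[[term]]
    if (anyDuplicated(ord))
      stop("age_resilience_scan: duplicate nodes in order '", term, "'")
    if (length(ord) < max_remove)
      stop("age_resilience_scan: order '", term, "' shorter than max_remove")
  }
  cells <- expand.grid(k = seq_len(max_remove), term = names(orders),
                       band = names(adjacency), stringsAsFactors = FALSE)
  M <- matrix(NA_real_, nrow = n_sub, ncol = nrow(cells))
  colnames(M) <- sprintf("%s|%s|%d", cells$band, cells$term, cells$k)
  for (b in names(adjacency)) {
    if (length(adjacency[[b]]) != n_sub)
      stop("age_resilience_scan: unequal subject counts across bands")
    for (term in names(orders)) {
      ord <- orders[[term]][seq_len(max_remove)]
      for (s in seq_len(n_sub)) {
        r <- attack(adjacency[[b]][[s]], ord)$r[-1L]   # drop r_0
        M[s, sprintf("%s|%s|%d", b, term, seq_len(max_remove))] <- r
      }
    }
  }
  corr <- maxstat_correction(M, ages, n_p = n_p, seed = seed)
  tab <- cbind(cells[, c("band", "term", "k")],
               node_removed = unlist(lapply(seq_len(nrow(cells)), function(z)
                 orders[[cells$term[z]]][cells$k[z]])),
               corr$table[, c("rho", "p_raw", "p_c")])
  snap <- do.call(rbind, lapply(split(tab, list(tab$band, tab$term)),
                                function(d) {
    i <- which.max(abs(d$rho))
    d[i, , drop = FALSE]
  }))
  rownames(snap) <- NULL
  structure(list(table = tab, snapshot = snap, correction = corr,
                 max_remove = max_remove),
            class = "resilience_scan")
}

#' @export
print.resilience_scan <- function(x, ...) {
  cat(sprintf("<resilience_scan> %d cell(s), snapshot(s):\n",
              nrow(x$table)))
  print(format(x$snapshot, digits = 3), row.names = FALSE)
  invisible(x)
}
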