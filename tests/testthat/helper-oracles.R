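# Independent brute-force oracles for the graph metrics, built from the
# literal matrix-power definitions: d_ij = min{ n : (A^n)_ij != 0 }, and
# sigma_mn = (A^{d_mn})_mn (walks of minimal length are exactly the simple
# shortest paths).  Deliberately distinct from the package's BFS/igraph
# implementations.

oracle_distances <- function(A) {
  n <- nrow(A)
  B <- (A != 0) * 1
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  P <- diag(n)
  for (s in seq_len(n)) {
    P <- P %*% B
    newly <- d == Inf & P != 0
    d[newly] <- s
  }
  diag(d) <- 0
  d
}

# sigma[m, n] = number of shortest paths from m to n (0 if unreachable)
oracle_sigma <- function(A) {
  n <- nrow(A)
  B <- (A != 0) * 1
  d <- oracle_distances(A)
  pow <- vector("list", n)
  P <- diag(n)
  for (s in seq_len(n)) {
    P <- P %*% B
    pow[[s]] <- P
  }
  sg <- matrix(0, n, n)
  for (m in seq_len(n)) for (k in seq_len(n)) {
    if (m != k && is.finite(d[m, k])) sg[m, k] <- pow[[d[m, k]]][m, k]
  }
  sg
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  d <- oracle_distances(A)
  sg <- oracle_sigma(A)
  b <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (m in seq_len(n - 1)) for (k in (m + 1):n) {
      if (m == i || k == i || !is.finite(d[m, k])) next
      if (is.finite(d[m, i]) && is.finite(d[i, k]) &&
          d[m, i] + d[i, k] == d[m, k])
        acc <- acc + sg[m, i] * sg[i, k] / sg[m, k]
    }
    b[i] <- acc
  }
  b
}

oracle_path_length <- function(A) {
  d <- oracle_distances(A)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  list(L = if (any(reach)) mean(off[reach]) else NA_real_,
       reachable_fraction = mean(reach))
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  d <- oracle_distances(A)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) 0 else
      oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

# triangle-count clustering: C_i = (A^3)_ii / (k_i (k_i - 1))
oracle_clustering <- function(A) {
  B <- (A != 0) * 1
  k <- rowSums(B)
  tri <- diag(B %*% B %*% B)
  ifelse(k < 2, 0, tri / (k * (k - 1)))
}

oracle_degree <- function(A) rowSums((A != 0) * 1)

random_graph <- function(n, p) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- ut[runif(length(ut)) < p]
  A[on] <- 1
  A + t(A)
}

# all labelled graphs on n nodes, as adjacency matrices (n small!)
all_graphs <- function(n) {
  n_pairs <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  lapply(0:(2^n_pairs - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_pairs)]
    A <- matrix(0, n, n)
    A[ut] <- bits
    A + t(A)
  })
}
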