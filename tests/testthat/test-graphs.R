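test_that("proportional thresholding retains the stated edge count", {
  set.seed(1)
  C <- matrix(rnorm(25), 5, 5); C <- C + t(C); diag(C) <- 0
  A <- threshold_proportional(C, 0.20)
  expect_equal(sum(A) / 2, 2)                    # round(0.2 * 10)
  expect_true(all(A %in% c(0, 1)))
  expect_equal(unclass(A), t(unclass(A)), ignore_attr = TRUE)
  expect_true(all(diag(A) == 0))

  A1 <- threshold_proportional(C, 1.0)
  expect_equal(sum(A1) / 2, 10)                  # complete graph

  # the two retained edges are the two strongest entries
  ut <- C[upper.tri(C)]
  expect_equal(sort(C[upper.tri(C) & A == 1]), sort(ut, decreasing = TRUE)[2:1])

  expect_error(threshold_proportional(C, 0), "cost")
  expect_error(threshold_proportional(C, 1.2), "cost")
})

test_that("thresholding ties break deterministically and density tracks cost", {
  allsame <- matrix(1, 6, 6); diag(allsame) <- 0
  A1 <- threshold_proportional(allsame, 0.4)
  A2 <- threshold_proportional(allsame, 0.4)
  expect_identical(A1, A2)
  expect_equal(sum(A1) / 2, round(0.4 * 15))

  set.seed(7)
  for (cost in c(0.05, 0.1, 0.25, 0.5)) {
    C <- matrix(rnorm(400), 20, 20); C <- C + t(C); diag(C) <- 0
    A <- threshold_proportional(C, cost)
    expect_lte(abs(sum(A) / 2 - cost * 190), 1)  # within one edge
  }
})

test_that("metric trivials match hand enumeration", {
  star <- star_graph(4)
  pathg <- path_graph(3)
  tri <- complete_graph(3)
  K4 <- complete_graph(4)
  K5 <- complete_graph(5)
  cyc4 <- matrix(0, 4, 4)
  cyc4[cbind(1:4, c(2, 3, 4, 1))] <- 1; cyc4 <- cyc4 + t(cyc4)

  expect_equal(as.numeric(path_length(K5)), 1)
  expect_equal(as.numeric(path_length(pathg)), 4 / 3)
  expect_equal(node_degree(star), c(4, 1, 1, 1, 1))
  expect_equal(clustering_coef(tri), rep(1, 3))
  expect_equal(clustering_coef(star), rep(0, 5))
  expect_equal(clustering_coef(cyc4), rep(0, 4))
  expect_equal(global_efficiency(K4), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(global_efficiency(pathg), 5 / 6)
  expect_equal(local_efficiency(K4), 1)
  expect_equal(local_efficiency(star), 0)
  expect_equal(betweenness_centrality(K5), rep(0, 5))
  expect_equal(betweenness_centrality(pathg), c(0, 1, 0))
  expect_equal(betweenness_centrality(star), c(6, 0, 0, 0, 0))

  # two disconnected edges: L over reachable pairs only
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
  L <- path_length(two)
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "reachable_fraction"), 1 / 3)
})

test_that("distances match the matrix-power oracle on random graphs", {
  set.seed(42)
  for (rep in 1:25) {
    A <- random_graph(sample(4:9, 1), runif(1, 0.15, 0.7))
    expect_equal(graph_distances(A), oracle_distances(A))
  }
})

test_that("every metric matches its brute-force oracle on random graphs", {
  set.seed(99)
  for (rep in 1:40) {
    A <- random_graph(sample(4:10, 1), runif(1, 0.1, 0.8))
    expect_equal(node_degree(A), oracle_degree(A))
    expect_equal(clustering_coef(A), oracle_clustering(A))
    expect_equal(global_efficiency(A), oracle_global_efficiency(A))
    expect_equal(local_efficiency(A, per_node = TRUE),
                 oracle_local_efficiency(A))
    expect_equal(betweenness_centrality(A), oracle_betweenness(A))
    o <- oracle_path_length(A)
    L <- path_length(A)
    expect_equal(as.numeric(L), o$L)
    expect_equal(attr(L, "reachable_fraction"), o$reachable_fraction)
  }
})

test_that("global efficiency is monotone under edge addition", {
  set.seed(5)
  for (rep in 1:20) {
    A <- random_graph(10, 0.2)
    e0 <- global_efficiency(A)
    off <- which(upper.tri(A) & A == 0)
    if (!length(off)) next
    pick <- sample(off, 1)
    A[pick] <- 1
    A[cbind(col(A)[pick], row(A)[pick])] <- 1
    A <- pmax(A, t(A))
    expect_gte(global_efficiency(A), e0)
  }
})

test_that("degree sum equals twice the edge count", {
  set.seed(8)
  for (rep in 1:10) {
    A <- random_graph(12, runif(1, 0.1, 0.9))
    expect_equal(sum(node_degree(A)), sum(A))
  }
})

test_that("graph_metrics bundles all metrics consistently", {
  set.seed(3)
  C <- matrix(rnorm(15 * 15), 15); C <- C + t(C); diag(C) <- 0
  A <- threshold_proportional(C, 0.25)
  gm <- graph_metrics(A)
  expect_s3_class(gm, "graph_metric_set")
  expect_equal(gm$degree, node_degree(A))
  expect_equal(gm$global_efficiency, global_efficiency(A))
  expect_equal(gm$local_efficiency, mean(gm$local_efficiency_node))
  expect_equal(gm$cost, 0.25)
  expect_true(all(gm$clustering >= 0 & gm$clustering <= 1))
  expect_true(all(gm$betweenness >= 0))
})

test_that("metric_grid produces the band x cost x metric layout", {
  set.seed(11)
  conn <- list(
    beta = lapply(1:4, function(i) {
      C <- matrix(rnorm(100), 10); C <- C + t(C); diag(C) <- 0; C
    }),
    gamma = lapply(1:4, function(i) {
      C <- matrix(rnorm(100), 10); C <- C + t(C); diag(C) <- 0; C
    }))
  M <- metric_grid(conn, costs = c(0.2, 0.4))
  expect_equal(dim(M), c(4, 2 * 2 * 2))
  expect_true(all(c("beta|0.2|global_efficiency",
                    "gamma|0.4|local_efficiency") %in% colnames(M)))
  A <- threshold_proportional(conn$beta[[2]], 0.4)
  expect_equal(unname(M[2, "beta|0.4|global_efficiency"]),
               global_efficiency(A))
  expect_equal(unname(M[2, "beta|0.4|local_efficiency"]),
               local_efficiency(A))
})
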