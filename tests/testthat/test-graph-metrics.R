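# Named graphs with hand-computable metrics.
k4 <- graph_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                               c(3, 4)))
star5 <- graph_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
path3 <- graph_from_edges(3, list(c(1, 2), c(2, 3)))
triangle <- graph_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))
two_k2 <- graph_from_edges(4, list(c(1, 2), c(3, 4)))
two_triangles <- graph_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                          c(4, 5), c(4, 6), c(5, 6)))

test_that("degree and handshake lemma", {
  expect_equal(node_degree(k4), rep(3L, 4))
  expect_equal(node_degree(star5), c(4L, 1L, 1L, 1L, 1L))
  adj <- random_adjacency(8, seed = 99)
  expect_equal(sum(node_degree(adj)), sum(adj))
})

test_that("closed-form global metrics on named graphs", {
  expect_equal(clustering_coefficient(triangle), 1.0)
  expect_equal(clustering_coefficient(star5), 0.0)
  expect_equal(characteristic_path_length(k4), 1.0)
  expect_equal(characteristic_path_length(path3), 4 / 3)
  expect_equal(global_efficiency(k4), 1.0)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(two_k2), 1 / 3)  # 2 of 6 pairs connected
  expect_equal(local_efficiency(k4), 1.0)
  expect_equal(local_efficiency(star5), 0.0)
  expect_equal(nodal_efficiency(k4), rep(1, 4))
  expect_equal(nodal_efficiency(path3)[1], (1 + 1 / 2) / 2)
  iso <- graph_from_edges(3, list(c(1, 2)))
  expect_equal(nodal_efficiency(iso)[3], 0)
})

test_that("betweenness follows the unordered-pairs unnormalized convention", {
  expect_equal(betweenness_centrality(star5), c(6, 0, 0, 0, 0))  # C(4,2)
  path5 <- graph_from_edges(5, lapply(1:4, function(i) c(i, i + 1)))
  expect_equal(betweenness_centrality(path5)[c(1, 5)], c(0, 0))
  expect_equal(betweenness_centrality(path5), c(0, 3, 4, 3, 0))
})

test_that("modularity: hand-computed and exhaustive cases", {
  # two disjoint triangles, component partition: Q = 2*(3/6 - (6/12)^2) = 0.5
  expect_equal(newman_q(two_triangles, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_gte(graph_modularity(two_triangles, seed = 1), 0.5 - 1e-9)
  expect_lt(abs(graph_modularity(k4, seed = 1)), 0.05)
  expect_error(graph_modularity(matrix(0L, 3, 3)), "edgeless")
  # two 5-cliques joined by one bridge: optimizer finds the exhaustive optimum
  bridged <- matrix(0L, 10, 10)
  bridged[1:5, 1:5] <- 1L; bridged[6:10, 6:10] <- 1L
  diag(bridged) <- 0L; bridged[5, 6] <- bridged[6, 5] <- 1L
  expect_equal(graph_modularity(bridged, seed = 2),
               newman_q(bridged, rep(1:2, each = 5)), tolerance = 1e-9)
})

test_that("every metric matches its brute-force oracle on random graphs", {
  for (i in 1:200) {
    n <- 4 + (i %% 5)  # 4..8 nodes
    adj <- random_adjacency(n, p = 0.25 + 0.5 * (i %% 7) / 6, seed = i)
    if (sum(adj) == 0) next
    expect_equal(clustering_coefficient(adj), oracle_clustering(adj),
                 info = paste("Cp, graph", i))
    expect_equal(global_efficiency(adj), oracle_eglob(adj),
                 info = paste("Eglob, graph", i))
    expect_equal(local_efficiency(adj), oracle_eloc(adj),
                 info = paste("Eloc, graph", i))
    expect_equal(nodal_efficiency(adj), oracle_nodal_eff(adj),
                 info = paste("Enod, graph", i))
    expect_equal(betweenness_centrality(adj), oracle_betweenness(adj),
                 tolerance = 1e-9, info = paste("BC, graph", i))
    d <- oracle_distances(adj)
    if (any(is.finite(d[upper.tri(d)]))) {
      expect_equal(characteristic_path_length(adj), oracle_lp(adj),
                   info = paste("Lp, graph", i))
    }
  }
})

test_that("modularity optimizer attains the exhaustive-search optimum", {
  for (i in seq(3, 60, by = 3)) {
    n <- 5 + (i %% 3)  # 5..7 nodes: exhaustive partition search is feasible
    adj <- random_adjacency(n, p = 0.5, seed = 1000 + i)
    if (sum(adj) == 0) next
    expect_equal(graph_modularity(adj, seed = i, n_restarts = 10),
                 oracle_modularity(adj), tolerance = 1e-9,
                 info = paste("Q, graph", i))
  }
})

test_that("degree-preserving rewiring preserves exactly what it must", {
  expect_equal(rewire_preserving_degree(triangle, seed = 5), triangle)
  adj <- random_adjacency(20, p = 0.3, seed = 42)
  r1 <- rewire_preserving_degree(adj, seed = 7)
  r2 <- rewire_preserving_degree(adj, seed = 7)
  r3 <- rewire_preserving_degree(adj, seed = 8)
  expect_identical(r1, r2)                      # deterministic per seed
  expect_false(identical(r1, r3))               # seed actually matters
  expect_equal(node_degree(r1), node_degree(adj))
  expect_equal(sum(r1), sum(adj))
  expect_true(all(diag(r1) == 0))
  expect_true(all(r1 %in% c(0L, 1L)))
})

test_that("normalization: self-ensemble gives gamma = lambda = sigma = 1", {
  adj <- random_adjacency(12, p = 0.4, seed = 3)
  cp <- clustering_coefficient(adj)
  lp <- characteristic_path_length(adj)
  expect_equal(cp / cp, 1)  # degenerate but fixes the definition
  gm <- global_metrics(adj, c("gamma", "lambda", "sigma"), n_random = 30,
                       seed = 11)
  expect_equal(unname(gm[["sigma"]]), unname(gm[["gamma"]] / gm[["lambda"]]))
})

test_that("small-world index separates lattice-like from random graphs", {
  # dense random graph is (in expectation) its own null: sigma near 1
  set.seed(5)
  er <- random_adjacency(68, p = 0.3, seed = 5)
  gm_er <- global_metrics(er, c("gamma", "lambda", "sigma"), n_random = 100,
                          seed = 2)
  expect_gt(gm_er[["sigma"]], 0.8)
  expect_lt(gm_er[["sigma"]], 1.2)
  # ring lattice (k = 8) with 5% seeded shortcut rewiring: small world
  n <- 68
  ring <- matrix(0L, n, n)
  for (i in seq_len(n)) for (off in 1:4) {
    j <- ((i + off - 1) %% n) + 1
    ring[i, j] <- ring[j, i] <- 1L
  }
  ws <- rewire_preserving_degree(ring, swaps_per_edge = 0.05, seed = 9)
  gm_ws <- global_metrics(ws, c("gamma", "lambda", "sigma"), n_random = 100,
                          seed = 3)
  expect_gt(gm_ws[["sigma"]], 1)
})

test_that("node relabeling permutes nodal metrics and fixes global ones", {
  adj <- random_adjacency(9, p = 0.4, seed = 77)
  set.seed(1)
  perm <- sample(9)
  padj <- adj[perm, perm]
  expect_equal(node_degree(padj), node_degree(adj)[perm])
  expect_equal(nodal_efficiency(padj), nodal_efficiency(adj)[perm])
  expect_equal(betweenness_centrality(padj),
               betweenness_centrality(adj)[perm], tolerance = 1e-9)
  expect_equal(clustering_coefficient(padj), clustering_coefficient(adj))
  expect_equal(characteristic_path_length(padj),
               characteristic_path_length(adj))
  expect_equal(global_efficiency(padj), global_efficiency(adj))
})

test_that("global efficiency is monotone under edge addition", {
  adj <- random_adjacency(10, p = 0.2, seed = 12)
  e0 <- global_efficiency(adj)
  free <- which(upper.tri(adj) & adj == 0)
  set.seed(2)
  add <- sample(free, 5)
  adj2 <- adj
  adj2[add] <- 1L
  adj2 <- pmax(adj2, t(adj2))
  expect_gte(global_efficiency(adj2), e0)
  expect_true(e0 >= 0 && global_efficiency(adj2) <= 1)
})

test_that("metric curves equal direct per-sparsity recomputation", {
  co <- small_synthetic(n_per_group = c(15, 15), n_blocks = 2, seed = 8,
                        regions = toy_regions(3))
  net <- correlation_matrix(residualize(co), "A")
  grid <- c(0.2, 0.3, 0.5)
  mc <- metric_curves(net, grid, metrics = c("Cp", "Lp", "Eglob"))
  for (s in seq_along(grid)) {
    adj <- binarize_at_sparsity(net, grid[s])
    expect_equal(unname(mc$values[s, "Cp"]), clustering_coefficient(adj))
    expect_equal(unname(mc$values[s, "Lp"]), characteristic_path_length(adj))
    expect_equal(unname(mc$values[s, "Eglob"]), global_efficiency(adj))
  }
  expect_equal(unname(mc$auc["Eglob"]),
               auc_trapezoid(mc$values[, "Eglob"], grid))
  # Eglob curve is non-decreasing in sparsity (nested edge sets)
  expect_true(all(diff(mc$values[, "Eglob"]) >= -1e-12))
})
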