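GLOBAL_METRICS <- c("Cp", "Lp", "gamma", "lambda", "sigma", "Eglob", "Eloc", "Q")
NODAL_METRICS <- c("degree", "nodal_efficiency", "betweenness")
NORMALIZED_METRICS <- c("gamma", "lambda", "sigma")

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
}

# All-pairs shortest-path matrix of a binary graph by repeated boolean
# matrix products (BLAS-backed; beats per-call graph-library overhead for
# the dense small/medium matrices this pipeline works on).
dense_distances <- function(adj) {
  n <- nrow(adj)
  A <- (adj > 0) + 0
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  cur <- A
  k <- 1
  while (k < n) {
    cur <- (cur %*% A > 0) + 0
    k <- k + 1
    new <- cur > 0 & !is.finite(d)
    if (!any(new)) break
    d[new] <- k
  }
  d
}

# Per-node Watts-Strogatz clustering from one matrix product:
# triangles at i = (A * A^2) row sum / 2.
dense_clustering <- function(adj) {
  A <- (adj > 0) + 0
  deg <- rowSums(A)
  tri2 <- rowSums(A * (A %*% A))  # 2 x triangles at each node
  ci <- ifelse(deg < 2, 0, tri2 / (deg * (deg - 1)))
  ci
}

#' Nodal degree
#' @param adj binary adjacency matrix
#' @return integer vector, one entry per node
#' @export
node_degree <- function(adj) as.integer(rowSums(adj > 0))

#' Mean clustering coefficient
#'
#' Watts-Strogatz binary clustering: per node, the fraction of realized edges
#' among its neighbors (nodes with degree < 2 contribute 0); Cp is the mean
#' over all nodes.
#'
#' @param adj binary adjacency matrix
#' @return scalar Cp
#' @export
clustering_coefficient <- function(adj) {
  mean(dense_clustering(adj))
}

pairwise_distances <- function(adj) {
  dense_distances(adj)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over node pairs, unit edge weights. In
#' disconnected graphs (possible at the lowest densities) only finite
#' distances are averaged.
#'
#' @param adj binary adjacency matrix
#' @return scalar Lp >= 1
#' @export
characteristic_path_length <- function(adj) {
  d <- pairwise_distances(adj)
  dv <- d[upper.tri(d)]
  dv <- dv[is.finite(dv)]
  if (length(dv) == 0) stop("no finite pairwise path: all nodes isolated")
  mean(dv)
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over all node pairs, with disconnected
#' pairs contributing 0; lies in `[0, 1]`.
#'
#' @param adj binary adjacency matrix
#' @return scalar Eglob
#' @export
global_efficiency <- function(adj) {
  d <- pairwise_distances(adj)
  inv <- 1 / d[upper.tri(d)]
  mean(ifelse(is.finite(inv), inv, 0))
}

#' Nodal efficiency
#'
#' For node i, the mean of 1/d(i, j) over all other nodes j (1/Inf = 0).
#'
#' @param adj binary adjacency matrix
#' @return numeric vector, one entry per node
#' @export
nodal_efficiency <- function(adj) {
  d <- pairwise_distances(adj)
  diag(d) <- Inf
  inv <- 1 / d
  rowSums(inv) / (nrow(adj) - 1)
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced on its neighbors
#' (0 for degree < 2); Eloc is the mean over all nodes.
#'
#' @param adj binary adjacency matrix
#' @return scalar Eloc
#' @export
local_efficiency <- function(adj) {
  deg <- rowSums(adj > 0)
  ei <- vapply(seq_len(nrow(adj)), function(i) {
    if (deg[i] < 2) return(0)
    nb <- which(adj[i, ] > 0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(ei)
}

#' Betweenness centrality
#'
#' For node v, the sum over unordered pairs (s, t), s != v != t, of the
#' fraction of shortest s-t paths passing through v; unnormalized.
#'
#' @param adj binary adjacency matrix
#' @return numeric vector, one entry per node
#' @export
betweenness_centrality <- function(adj) {
  as.numeric(igraph::betweenness(as_igraph(adj), directed = FALSE,
                                 normalized = FALSE))
}

#' Modularity of the best partition found by Louvain optimization
#'
#' Newman modularity Q of the best community partition across `n_restarts`
#' seeded restarts of multilevel (Louvain) optimization, each restart visiting
#' nodes in a different random order. Only Q is reported; the partition is an
#' implementation detail.
#'
#' @param adj binary adjacency matrix
#' @param seed integer seed
#' @param n_restarts number of restarts (default 10)
#' @return scalar Q
#' @export
graph_modularity <- function(adj, seed = 1L, n_restarts = 10L) {
  g <- as_igraph(adj)
  if (igraph::ecount(g) == 0) stop("modularity undefined for an edgeless graph")
  best <- -Inf
  n <- igraph::vcount(g)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    q <- max(cl$modularity)
    if (q > best) best <- q
  }
  best
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Randomizes a binary graph by repeated double-edge swaps that preserve every
#' node's degree exactly; swaps creating self-loops or multi-edges are
#' rejected. Deterministic given the seed.
#'
#' @param adj binary adjacency matrix
#' @param swaps_per_edge attempted swaps per edge (default 10)
#' @param seed integer seed
#' @return rewired adjacency matrix with identical degree sequence
#' @export
rewire_preserving_degree <- function(adj, swaps_per_edge = 10L, seed = 1L) {
  g <- as_igraph(adj)
  set.seed(seed)
  gr <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = max(1L, swaps_per_edge * igraph::ecount(g))))
  out <- as.matrix(igraph::as_adjacency_matrix(gr, type = "both"))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(adj)
  out
}

#' Global metrics of one binary graph, with null-model normalization
#'
#' Computes Cp, Lp, Eglob, Eloc and Q, then normalizes Cp and Lp against the
#' mean over an ensemble of degree-preserving rewired null networks:
#' `gamma = Cp / mean(Cp_rand)`, `lambda = Lp / mean(Lp_rand)`, and the
#' small-world index `sigma = gamma / lambda`.
#'
#' @param adj binary adjacency matrix
#' @param metrics which global metrics to compute (default all)
#' @param n_random null-ensemble size (default 100); ignored when no
#'   normalized metric is requested
#' @param swaps_per_edge rewiring intensity (default 10)
#' @param seed integer master seed; ensemble seeds are derived by fixed
#'   increments
#' @param n_restarts Louvain restarts for Q
#' @return named numeric vector of the requested metrics
#' @export
global_metrics <- function(adj, metrics = GLOBAL_METRICS, n_random = 100L,
                           swaps_per_edge = 10L, seed = 1L, n_restarts = 10L) {
  metrics <- match.arg(metrics, GLOBAL_METRICS, several.ok = TRUE)
  out <- c()
  need_norm <- any(metrics %in% NORMALIZED_METRICS)
  need_cp <- any(c("Cp", "gamma", "sigma") %in% metrics)
  need_lp <- any(c("Lp", "lambda", "sigma") %in% metrics)
  mean_finite_lp <- function(d) {
    dv <- d[upper.tri(d)]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0) stop("no finite pairwise path: all nodes isolated")
    mean(dv)
  }
  cp <- if (need_cp) clustering_coefficient(adj) else NA_real_
  lp <- if (need_lp) mean_finite_lp(dense_distances(adj)) else NA_real_
  if (need_norm) {
    # rewiring runs in igraph's C core; metrics on each null network go
    # through the dense matrix path (edge list -> adjacency)
    g <- as_igraph(adj)
    n <- nrow(adj)
    cps <- lps <- numeric(n_random)
    niter <- max(1L, as.integer(swaps_per_edge * igraph::ecount(g)))
    set.seed(seed)
    for (b in seq_len(n_random)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                     niter = niter))
      el <- igraph::as_edgelist(gr, names = FALSE)
      radj <- matrix(0, n, n)
      radj[el] <- 1
      radj <- radj + t(radj)
      if (need_cp) cps[b] <- clustering_coefficient(radj)
      if (need_lp) lps[b] <- mean_finite_lp(dense_distances(radj))
    }
    gamma <- cp / mean(cps)
    lambda <- lp / mean(lps)
    out <- c(out, gamma = gamma, lambda = lambda, sigma = gamma / lambda)
  }
  out <- c(out, Cp = cp, Lp = lp)
  if ("Eglob" %in% metrics) out <- c(out, Eglob = global_efficiency(adj))
  if ("Eloc" %in% metrics) out <- c(out, Eloc = local_efficiency(adj))
  if ("Q" %in% metrics) {
    out <- c(out, Q = graph_modularity(adj, seed = seed, n_restarts = n_restarts))
  }
  out[metrics]
}

#' Nodal metrics of one binary graph
#' @param adj binary adjacency matrix
#' @param metrics which nodal metrics (default all three)
#' @return matrix, nodes x metrics
#' @export
nodal_metrics <- function(adj, metrics = NODAL_METRICS) {
  metrics <- match.arg(metrics, NODAL_METRICS, several.ok = TRUE)
  cols <- lapply(metrics, function(m) switch(m,
    degree = node_degree(adj),
    nodal_efficiency = nodal_efficiency(adj),
    betweenness = betweenness_centrality(adj)))
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(adj), metrics)
  out
}

#' Global metric curves over a sparsity grid
#'
#' Thresholds a covariance network at every sparsity of the grid and computes
#' the requested global metrics on each binary graph; each curve is summarized
#' by its trapezoidal AUC over the grid. Sparsities that map to the same edge
#' count yield the same graph and are computed once.
#'
#' @param net a `cov_network`
#' @param grid sparsity grid from [sparsity_grid()]
#' @param metrics global metrics to evaluate
#' @param n_random,swaps_per_edge,seed,n_restarts null-ensemble settings
#'   passed to [global_metrics()]
#' @return list with `grid`, `values` (sparsities x metrics matrix) and
#'   `auc` (named vector)
#' @export
metric_curves <- function(net, grid = sparsity_grid(),
                          metrics = GLOBAL_METRICS, n_random = 100L,
                          swaps_per_edge = 10L, seed = 1L, n_restarts = 10L) {
  R <- nrow(net$matrix)
  ks <- vapply(grid, edge_count_at, integer(1), n_regions = R)
  if (any(ks == 0)) stop("grid contains a sparsity with no edges")
  ranking <- edge_ranking(net$matrix)  # rank once, slice per edge count
  vals <- matrix(NA_real_, length(grid), length(metrics),
                 dimnames = list(NULL, metrics))
  cache <- list()
  for (s in seq_along(grid)) {
    key <- as.character(ks[s])
    if (is.null(cache[[key]])) {
      adj <- matrix(0L, R, R, dimnames = dimnames(net$matrix))
      adj[ranking[seq_len(ks[s])]] <- 1L
      adj <- adj + t(adj)
      cache[[key]] <- global_metrics(adj, metrics, n_random = n_random,
                                     swaps_per_edge = swaps_per_edge,
                                     seed = seed + 1000L * s,
                                     n_restarts = n_restarts)
    }
    vals[s, ] <- cache[[key]]
  }
  list(grid = grid, values = vals,
       auc = apply(vals, 2, auc_trapezoid, grid = grid))
}

#' Nodal metric curves over a sparsity grid
#'
#' @inheritParams metric_curves
#' @param metrics nodal metrics to evaluate
#' @return list with `grid`, `values` (3-d array: sparsity x node x metric)
#'   and `auc` (node x metric matrix)
#' @export
nodal_metric_curves <- function(net, grid = sparsity_grid(),
                                metrics = NODAL_METRICS) {
  R <- nrow(net$matrix)
  vals <- array(NA_real_, c(length(grid), R, length(metrics)),
                dimnames = list(NULL, net$regions$id, metrics))
  for (s in seq_along(grid)) {
    adj <- binarize_at_sparsity(net, grid[s])
    vals[s, , ] <- nodal_metrics(adj, metrics)
  }
  auc <- apply(vals, c(2, 3), auc_trapezoid, grid = grid)
  list(grid = grid, values = vals, auc = auc)
}
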