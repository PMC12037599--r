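# Independent brute-force oracles for graph metrics. Deliberately naive:
# Floyd-Warshall distances, O(n^3) triangle counting, exhaustive shortest-path
# enumeration and exhaustive partition search, so they share no code path with
# the implementation they check.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  dv <- d[upper.tri(d)]
  mean(dv[is.finite(dv)])
}

oracle_eglob <- function(adj) {
  d <- oracle_distances(adj)
  iv <- 1 / d[upper.tri(d)]
  mean(ifelse(is.finite(iv), iv, 0))
}

oracle_nodal_eff <- function(adj) {
  d <- oracle_distances(adj)
  diag(d) <- Inf
  rowSums(1 / d) / (nrow(adj) - 1)
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_along(nb))
      for (b in seq_len(a - 1))
        if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
    ci[v] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

oracle_eloc <- function(adj) {
  n <- nrow(adj)
  ei <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) next
    ei[v] <- oracle_eglob(adj[nb, nb, drop = FALSE])
  }
  mean(ei)
}

# Betweenness by explicit enumeration of all shortest paths (DFS over the
# BFS predecessor structure); endpoints excluded, unordered pairs.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  enumerate_paths <- function(s, t) {
    if (!is.finite(d[s, t])) return(list())
    if (s == t) return(list(s))
    paths <- list()
    for (w in which(adj[t, ] > 0)) {
      if (d[s, w] == d[s, t] - 1) {
        for (p in enumerate_paths(s, w)) paths <- c(paths, list(c(p, t)))
      }
    }
    paths
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_paths(s, t)
    if (length(paths) == 0) next
    inner <- table(factor(unlist(lapply(paths, function(p) p[-c(1, length(p))])),
                          levels = seq_len(n)))
    bc <- bc + as.numeric(inner) / length(paths)
  }
  bc
}

newman_q <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    q <- q + sum(adj[idx, idx]) / (2 * m) - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# Exhaustive modularity: maximum Newman Q over every partition of the nodes
# (restricted set-partition enumeration; feasible for n <= 8).
oracle_modularity <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  assign_next <- function(membership, i, k) {
    if (i > n) {
      q <- newman_q(adj, membership)
      if (q > best) best <<- q
      return(invisible())
    }
    for (cc in seq_len(k + 1)) {
      membership[i] <- cc
      assign_next(membership, i + 1, max(k, cc))
    }
  }
  assign_next(integer(n), 1L, 0L)
  best
}

# Seeded random connected-ish test graph as an adjacency matrix.
random_adjacency <- function(n, p = 0.45, seed = 1) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

graph_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  adj
}
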