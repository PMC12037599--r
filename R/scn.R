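#' Sparsity grid
#'
#' The density grid over which binary networks are built and metric curves
#' integrated: 0.10 to 0.40 in steps of 0.01 by default.
#'
#' @param start,stop,step grid parameters; both endpoints are included.
#' @return numeric vector of sparsities, strictly increasing.
#' @export
sparsity_grid <- function(start = 0.10, stop = 0.40, step = 0.01) {
  if (!(start > 0 && start <= stop && stop <= 1 && step > 0)) {
    stop("require 0 < start <= stop <= 1 and step > 0")
  }
  n <- floor((stop - start) / step + 1e-9)
  grid <- start + step * (0:n)
  if (grid[length(grid)] < stop - 1e-9) grid <- c(grid, stop)
  round(grid, 10)
}

#' Group-level structural covariance matrix
#'
#' Across the subjects of one group, computes the Pearson correlation between
#' every pair of regional values and takes its absolute value, so that edge
#' weight reflects covariance strength regardless of direction. The diagonal
#' is fixed at 0.
#'
#' @param cohort a (typically residualized) [morph_cohort()]
#' @param group group level to use
#' @return an object of class `cov_network`: list with `matrix` (R x R,
#'   entries in `[0, 1]`), `group`, `n_subjects`, `regions`.
#' @export
correlation_matrix <- function(cohort, group) {
  vals <- group_values(cohort, group)
  if (nrow(vals) < 4) stop("group '", group, "' has fewer than 4 subjects")
  cm <- colMeans(vals)
  sds <- sqrt(colSums(sweep(vals, 2, cm)^2) / (nrow(vals) - 1))
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(utils::head(colnames(vals)[sds == 0], 5), collapse = ", "))
  }
  m <- abs(stats::cor(vals))
  diag(m) <- 0
  dimnames(m) <- list(colnames(vals), colnames(vals))
  structure(list(matrix = m, group = as.character(group),
                 n_subjects = nrow(vals), regions = cohort$regions),
            class = "cov_network")
}

#' @export
print.cov_network <- function(x, ...) {
  cat("<cov_network> group ", x$group, ": ", nrow(x$matrix), "x",
      ncol(x$matrix), " |Pearson r|, n = ", x$n_subjects, "\n", sep = "")
  invisible(x)
}

#' Number of edges retained at a sparsity
#'
#' `k = round(s * R(R-1)/2)` with half-up rounding, so the edge count depends
#' only on the sparsity and the node count — any two groups thresholded at the
#' same density have identical edge counts by construction.
#'
#' @param sparsity density in (0, 1]
#' @param n_regions node count
#' @return integer edge count
#' @export
edge_count_at <- function(sparsity, n_regions) {
  as.integer(floor(sparsity * n_regions * (n_regions - 1) / 2 + 0.5))
}

# Rank the upper-triangle entries of a weight matrix: descending weight,
# ties broken by (row, col) lexicographic index so thresholding is
# deterministic and edge sets are nested across sparsities.
edge_ranking <- function(m) {
  R <- nrow(m)
  ut <- which(upper.tri(m))
  i <- ((ut - 1) %% R) + 1
  j <- ((ut - 1) %/% R) + 1
  ut[order(-m[ut], i, j)]
}

#' Threshold a covariance network into a binary graph
#'
#' Keeps exactly [edge_count_at()] edges with the largest absolute
#' correlations (ties broken deterministically by node index) and sets all
#' others to zero, giving an undirected, unweighted adjacency matrix.
#'
#' @param net a `cov_network` from [correlation_matrix()]
#' @param sparsity density in (0, 1]
#' @return adjacency matrix (0/1 integer, symmetric, zero diagonal) with
#'   attributes `sparsity` and `n_edges`
#' @export
binarize_at_sparsity <- function(net, sparsity) {
  stopifnot(inherits(net, "cov_network"))
  if (!(sparsity > 0 && sparsity <= 1)) stop("sparsity must be in (0, 1]")
  m <- net$matrix
  R <- nrow(m)
  k <- edge_count_at(sparsity, R)
  if (k == 0) stop("sparsity ", sparsity, " gives an empty network")
  keep <- edge_ranking(m)[seq_len(k)]
  adj <- matrix(0L, R, R, dimnames = dimnames(m))
  adj[keep] <- 1L
  adj <- adj + t(adj)
  attr(adj, "sparsity") <- sparsity
  attr(adj, "n_edges") <- k
  adj
}

#' Export a covariance or adjacency matrix as a TSV edge list
#' @param m square matrix with region ids as dimnames
#' @param path output file
#' @return invisibly, the edge-list data.frame
#' @export
write_edge_list <- function(m, path) {
  ut <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  el <- data.frame(region_a = rownames(m)[ut[, 1]],
                   region_b = colnames(m)[ut[, 2]],
                   weight = m[ut])
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(el)
}
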