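#' Trapezoidal area under a metric-by-sparsity curve
#'
#' Integrates a curve over its sparsity grid with the trapezoidal rule,
#' summarizing a metric across the whole density range in one
#' threshold-independent statistic.
#'
#' @param values metric values at each grid point
#' @param grid strictly increasing sparsity grid
#' @return scalar AUC
#' @export
auc_trapezoid <- function(values, grid) {
  stopifnot(length(values) == length(grid))
  if (length(grid) < 2) return(0)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  sum((values[-1] + values[-length(values)]) / 2 * diff(grid))
}

# Random relabeling of subjects into two groups of the original sizes.
permute_labels <- function(group, seed) {
  set.seed(seed)
  factor(sample(as.character(group)), levels = levels(group))
}

#' Randomly reassign subjects to two new groups of the original sizes
#'
#' The permutation-null primitive: subjects keep their (corrected) values and
#' receive shuffled group labels, preserving the two group sizes exactly.
#'
#' @param cohort a [morph_cohort()]
#' @param seed integer seed (deterministic relabeling)
#' @return the cohort with permuted group labels
#' @export
permute_groups <- function(cohort, seed) {
  out <- cohort
  out$group <- permute_labels(cohort$group, seed)
  out
}

# AUC of one global metric for both groups under given labels: the full
# pipeline (correlation -> binarize -> metric -> AUC) is re-run per group.
group_metric_aucs <- function(cohort, metric, grid, n_random, swaps_per_edge,
                              seed, n_restarts) {
  vapply(levels(cohort$group), function(g) {
    net <- correlation_matrix(cohort, g)
    metric_curves(net, grid, metrics = metric, n_random = n_random,
                  swaps_per_edge = swaps_per_edge, seed = seed,
                  n_restarts = n_restarts)$auc[[metric]]
  }, numeric(1))
}

#' Two-group permutation test on a global metric's AUC
#'
#' The observed statistic is `AUC(group A) - AUC(group B)` of the metric
#' curve over the sparsity grid (A = first group level). The null is built by
#' repeatedly reassigning subjects at random to two groups of the original
#' sizes and re-running the whole pipeline (correlation, thresholding,
#' metrics, AUC) on each relabeling. The two-tailed p-value uses the add-one
#' estimator `(1 + #{|null| >= |observed|}) / (repetitions + 1)`, so p is
#' never 0; the 95% band is the 2.5-97.5 percentile interval of the null.
#'
#' Normalized metrics (gamma, lambda, sigma) need a rewired null ensemble at
#' every sparsity: the observed statistic uses `n_random` networks and each
#' permutation uses the cheaper `null_per_perm`.
#'
#' @param cohort a corrected [morph_cohort()]
#' @param metric one global metric name
#' @param grid sparsity grid
#' @param repetitions number of relabelings (default 2000; warning below 1000,
#'   error below 100)
#' @param seed master seed; every permutation and ensemble seed derives from it
#' @param n_random null-ensemble size for the observed statistic (default 100)
#' @param null_per_perm null-ensemble size inside each permutation (default 20)
#' @param swaps_per_edge rewiring intensity
#' @param n_restarts Louvain restarts for Q
#' @return object of class `perm_test`: list with `metric`, `observed`
#'   (named per-group AUCs), `diff`, `null` (vector), `p`, `band`
#' @export
global_permutation_test <- function(cohort, metric, grid = sparsity_grid(),
                                    repetitions = 2000L, seed = 1L,
                                    n_random = 100L, null_per_perm = 20L,
                                    swaps_per_edge = 10L, n_restarts = 10L) {
  metric <- match.arg(metric, GLOBAL_METRICS)
  if (repetitions < 100) stop("need at least 100 repetitions")
  if (repetitions < 1000) {
    warning("fewer than 1000 repetitions: p-value resolution is coarse")
  }
  seeds <- derive_seeds(seed, repetitions + 1L)
  observed <- group_metric_aucs(cohort, metric, grid, n_random,
                                swaps_per_edge, seeds[1], n_restarts)
  obs_diff <- observed[[1]] - observed[[2]]
  null <- vapply(seq_len(repetitions), function(b) {
    perm <- permute_groups(cohort, seeds[b + 1L])
    aucs <- group_metric_aucs(perm, metric, grid, null_per_perm,
                              swaps_per_edge, seeds[b + 1L], n_restarts)
    aucs[[1]] - aucs[[2]]
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs_diff))) / (repetitions + 1)
  structure(list(metric = metric, observed = observed, diff = obs_diff,
                 null = null, p = p,
                 band = stats::quantile(null, c(0.025, 0.975), names = FALSE)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$metric, "-AUC: ",
      paste(sprintf("%s = %.4f", names(x$observed), x$observed),
            collapse = ", "),
      sprintf("; diff = %+.4f, p = %.4g (%d permutations), 95%% band [%.4f, %.4f]\n",
              x$diff, x$p, length(x$null), x$band[1], x$band[2]), sep = "")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1 (delegates to
#' [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of raw p-values
#' @return adjusted p-values, same order as input
#' @export
bh_fdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Per-region permutation test on a nodal metric, with FDR correction
#'
#' Compares the two groups region by region on one nodal metric evaluated at
#' a single sparsity (default 0.10, the lower end of the analysis range).
#' Per-region two-tailed permutation p-values (add-one estimator) are adjusted
#' across regions with Benjamini-Hochberg; regions with adjusted p < `alpha`
#' are flagged.
#'
#' @param cohort a corrected [morph_cohort()]
#' @param metric one of `degree`, `nodal_efficiency`, `betweenness`
#' @param sparsity single density at which the graphs are compared
#' @param repetitions number of relabelings
#' @param seed master seed
#' @param alpha significance level on the adjusted p-values
#' @return data.frame with one row per region: observed per-group values,
#'   difference, raw and BH-adjusted p, significance flag
#' @export
nodal_permutation_test_fdr <- function(cohort, metric = NODAL_METRICS,
                                       sparsity = 0.10, repetitions = 1000L,
                                       seed = 1L, alpha = 0.05) {
  metric <- match.arg(metric, NODAL_METRICS)
  if (repetitions < 100) stop("need at least 100 repetitions")
  groups <- levels(cohort$group)
  nodal_at <- function(coh) {
    vapply(groups, function(g) {
      adj <- binarize_at_sparsity(correlation_matrix(coh, g), sparsity)
      nodal_metrics(adj, metric)[, 1]
    }, numeric(nrow(cohort$regions)))
  }
  obs <- nodal_at(cohort)
  obs_diff <- obs[, 1] - obs[, 2]
  seeds <- derive_seeds(seed, repetitions)
  exceed <- integer(length(obs_diff))
  for (b in seq_len(repetitions)) {
    perm_obs <- nodal_at(permute_groups(cohort, seeds[b]))
    exceed <- exceed + (abs(perm_obs[, 1] - perm_obs[, 2]) >= abs(obs_diff))
  }
  p_raw <- (1 + exceed) / (repetitions + 1)
  p_bh <- bh_fdr(p_raw)
  out <- data.frame(region = cohort$regions$id,
                    metric = metric, sparsity = sparsity,
                    group_a = obs[, 1], group_b = obs[, 2], diff = obs_diff,
                    p_raw = p_raw, p_bh = p_bh,
                    significant = p_bh < alpha,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "group_a"] <- groups[1]
  names(out)[names(out) == "group_b"] <- groups[2]
  rownames(out) <- NULL
  out
}
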