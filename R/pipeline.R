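#' Assemble a validated pipeline configuration
#'
#' @param cohorts named list of [morph_cohort()] objects, keyed by basis
#'   (e.g. `CSA`, `CT`); alternatively supply `paths`, a named list of
#'   `list(morph =, meta =)` pairs to be loaded.
#' @param out_dir output directory for all report files
#' @param covariates,pooled residualization settings (see [residualize()])
#' @param grid sparsity grid
#' @param metrics global metrics to test
#' @param nodal_metrics nodal metrics to test
#' @param nodal_sparsity single density for the nodal comparison
#' @param repetitions permutation count
#' @param n_random,null_per_perm,swaps_per_edge null-ensemble sizes
#' @param seed master seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(cohorts = NULL, out_dir = "results",
                            covariates = c("age", "sex"), pooled = TRUE,
                            grid = sparsity_grid(),
                            metrics = GLOBAL_METRICS,
                            nodal_metrics = NODAL_METRICS,
                            nodal_sparsity = 0.10, repetitions = 2000L,
                            n_random = 100L, null_per_perm = 20L,
                            swaps_per_edge = 10L, seed = 1L, paths = NULL) {
  if (is.null(cohorts) && is.null(paths)) stop("supply cohorts or paths")
  if (is.null(cohorts)) {
    cohorts <- lapply(paths, function(p) load_cohort(p$morph, p$meta))
  }
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    stop("cohorts must be a named list (e.g. CSA =, CT =)")
  }
  stopifnot(all(vapply(cohorts, inherits, logical(1), "morph_cohort")))
  structure(list(cohorts = cohorts, out_dir = out_dir,
                 covariates = covariates, pooled = pooled, grid = grid,
                 metrics = metrics, nodal_metrics = nodal_metrics,
                 nodal_sparsity = nodal_sparsity,
                 repetitions = as.integer(repetitions),
                 n_random = as.integer(n_random),
                 null_per_perm = as.integer(null_per_perm),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Per-region pooled t-test on raw regional values with BH correction: a
# region-level surrogate for vertex-wise morphometric comparison (which needs
# the surfaces themselves and is out of scope here).
roi_group_tests <- function(cohort) {
  groups <- levels(cohort$group)
  res <- lapply(cohort$regions$id, function(rid) {
    v <- cohort$values[, rid]
    ht <- stats::t.test(v[cohort$group == groups[1]],
                        v[cohort$group == groups[2]], var.equal = TRUE)
    data.frame(region = rid, mean_a = ht$estimate[[1]],
               mean_b = ht$estimate[[2]], t = unname(ht$statistic),
               p = ht$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- bh_fdr(out$p)
  names(out)[2:3] <- paste0("mean_", groups)
  rownames(out) <- NULL
  out
}

#' Run the full structural covariance network analysis
#'
#' For every cohort basis in the configuration: demographics table, per-region
#' group comparison (BH-corrected), covariate residualization, per-group
#' covariance networks, global metric curves, AUC permutation tests for every
#' requested global metric, and the FDR-corrected nodal comparison. All
#' results are written as TSV under `out_dir`, alongside a JSON copy of the
#' configuration for provenance.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a nested list of all results
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- config
  prov$cohorts <- lapply(config$cohorts, function(co) {
    list(n = length(co$subjects), groups = as.list(table(co$group)),
         metric = co$metric)
  })
  jsonlite::write_json(unclass(prov), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  results <- list()
  for (basis in names(config$cohorts)) {
    cohort <- config$cohorts[[basis]]
    message("[", basis, "] ", length(cohort$subjects), " subjects, groups: ",
            paste(table(cohort$group), collapse = "/"))
    pre <- function(name) file.path(config$out_dir, paste0(basis, "_", name))
    tab1 <- clinical_table(cohort)
    write_tsv(tab1, pre("clinical_table.tsv"))
    roi <- roi_group_tests(cohort)
    write_tsv(roi, pre("roi_group_tests.tsv"))
    corrected <- residualize(cohort, config$covariates, config$pooled)
    nets <- lapply(levels(cohort$group),
                   function(g) correlation_matrix(corrected, g))
    names(nets) <- levels(cohort$group)
    for (g in names(nets)) {
      m <- nets[[g]]$matrix
      utils::write.table(cbind(region = rownames(m), as.data.frame(m)),
                         pre(paste0("covariance_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    curves <- lapply(nets, metric_curves, grid = config$grid,
                     metrics = config$metrics, n_random = config$n_random,
                     swaps_per_edge = config$swaps_per_edge,
                     seed = config$seed)
    curve_tab <- do.call(rbind, lapply(names(curves), function(g) {
      data.frame(group = g,
                 sparsity = rep(config$grid, length(config$metrics)),
                 metric = rep(config$metrics, each = length(config$grid)),
                 value = as.vector(curves[[g]]$values))
    }))
    write_tsv(curve_tab, pre("global_curves.tsv"))
    perm <- lapply(config$metrics, function(m) {
      message("[", basis, "] permutation test: ", m, "-AUC (",
              config$repetitions, " repetitions)")
      global_permutation_test(corrected, m, config$grid,
                              repetitions = config$repetitions,
                              seed = config$seed,
                              n_random = config$n_random,
                              null_per_perm = config$null_per_perm,
                              swaps_per_edge = config$swaps_per_edge)
    })
    names(perm) <- config$metrics
    perm_tab <- do.call(rbind, lapply(perm, function(pt) {
      data.frame(basis = basis, metric = pt$metric,
                 auc_a = pt$observed[[1]], auc_b = pt$observed[[2]],
                 diff = pt$diff, p = pt$p,
                 band_lo = pt$band[1], band_hi = pt$band[2])
    }))
    names(perm_tab)[3:4] <- paste0("auc_", levels(cohort$group))
    rownames(perm_tab) <- NULL
    write_tsv(perm_tab, pre("global_permutation.tsv"))
    nodal <- do.call(rbind, lapply(config$nodal_metrics, function(m) {
      nodal_permutation_test_fdr(corrected, m,
                                 sparsity = config$nodal_sparsity,
                                 repetitions = config$repetitions,
                                 seed = config$seed)
    }))
    write_tsv(nodal, pre("nodal_fdr.tsv"))
    results[[basis]] <- list(clinical = tab1, roi = roi, networks = nets,
                             curves = curves, global = perm_tab,
                             nodal = nodal)
  }
  invisible(results)
}
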