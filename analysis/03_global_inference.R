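#!/usr/bin/env Rscript
# Two-group comparison of the global network metrics by AUC permutation
# testing (subject relabeling, full pipeline re-run per relabeling). The
# simulated cohorts are null, so p-values should be spread over (0, 1] and
# significant results should appear at roughly the nominal 5% rate.
# Permutation count is reduced from the reference 2000 to 200 to keep this
# driver quick; raise `reps` for final figures.

suppressMessages(library(scnets))
seed <- 7L
reps <- 200L
dir.create("results/inference", recursive = TRUE, showWarnings = FALSE)

for (stem in c("csa", "ct")) {
  cohort <- suppressWarnings(suppressMessages(load_cohort(
    sprintf("results/fixtures/%s_%s.tsv", stem,
            if (stem == "csa") "area" else "thickness"),
    sprintf("results/fixtures/%s_meta.tsv", stem))))
  corrected <- residualize(cohort)
  rows <- lapply(c("Lp", "Eglob", "Eloc", "Cp", "lambda", "sigma"),
                 function(m) {
    pt <- suppressWarnings(global_permutation_test(
      corrected, m, repetitions = reps, seed = seed,
      n_random = 50L, null_per_perm = 3L))
    message(sprintf("[%s] %s-AUC: A = %.4f, B = %.4f, diff = %+.4f, p = %.3f",
                    stem, m, pt$observed[[1]], pt$observed[[2]], pt$diff, pt$p))
    data.frame(basis = toupper(stem), metric = m,
               auc_A = pt$observed[[1]], auc_B = pt$observed[[2]],
               diff = pt$diff, p = pt$p,
               band_lo = pt$band[1], band_hi = pt$band[2])
  })
  utils::write.table(do.call(rbind, rows),
    sprintf("results/inference/%s_global_permutation.tsv", stem),
    sep = "\t", quote = FALSE, row.names = FALSE)
}
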