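#!/usr/bin/env Rscript
# Demographic/clinical group comparisons (Shapiro-Wilk gated t vs
# Mann-Whitney) and the exploratory region-by-clinical partial correlation
# screen (age- and sex-adjusted), per group, on the simulated surface-area
# cohort. Also reproduces two printed-statistic checks from group summaries.

suppressMessages(library(scnets))
dir.create("results/clinical", recursive = TRUE, showWarnings = FALSE)

cohort <- suppressWarnings(suppressMessages(load_cohort(
  "results/fixtures/csa_area.tsv", "results/fixtures/csa_meta.tsv")))

tab <- clinical_table(cohort)
utils::write.table(tab, "results/clinical/group_comparisons.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("clinical table: %d variables, %d via t-test, %d via Mann-Whitney",
                nrow(tab), sum(tab$test == "t_test"),
                sum(tab$test == "mann_whitney")))

cors <- do.call(rbind, lapply(levels(cohort$group), function(g)
  clinical_correlations(cohort, g,
                        regions = c("rh_precuneus", "rh_supramarginal",
                                    "lh_inferiorparietal", "lh_lingual"),
                        clinical_vars = c("onset_age", "duration", "updrs3",
                                          "pdq39", "bdi", "mmse", "ledd"))))
utils::write.table(cors, "results/clinical/partial_correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("partial correlations: %d tests, %d with p < 0.05 (uncorrected)",
                nrow(cors), sum(cors$p < 0.05)))

# printed-summary checks: pooled t from published-style group summaries and
# the p-value of a partial correlation given (r, n, k)
st <- summary_t_test(822.470, 361.0314, 50, 813.286, 341.9414, 49)
message(sprintf("summary pooled t-test check: t = %.3f, p = %.3f",
                st$statistic, st$p))
message(sprintf("partial r = 0.360 (n = 50, k = 2): p = %.4f",
                partial_r_pvalue(0.360, 50, 2)))
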