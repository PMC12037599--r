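#!/usr/bin/env Rscript
# Simulate the two morphometric cohorts the analysis runs on: a surface-area
# (CSA-like) and a thickness (CT-like) cohort of 50 + 49 subjects x 68
# Desikan regions with block-structured covariance, age/sex effects and
# plausible clinical scores. Writes reloadable TSV fixtures plus ground-truth
# manifests under results/fixtures/.

suppressMessages(library(scnets))
seed <- 20260925L

for (metric in c("surface_area_mm2", "thickness_mm")) {
  stem <- if (metric == "surface_area_mm2") "csa" else "ct"
  # distinct seeds so the two bases are independent cohorts
  spec <- synthetic_spec(metric = metric,
                         seed = seed + (metric == "thickness_mm"))
  cohort <- suppressWarnings(generate_cohort(spec))
  paths <- write_fixture(cohort, "results/fixtures", stem)
  message(sprintf("[%s] %d subjects x %d regions (groups %s) -> %s",
                  stem, nrow(cohort$values), ncol(cohort$values),
                  paste(table(cohort$group), collapse = "/"),
                  paths[["morph"]]))
}
message("Both cohorts are null (group effect multiplier 1): any downstream ",
        "group difference is sampling noise.")
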