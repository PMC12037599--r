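# Small cohorts built in code for the unit tests.

toy_regions <- function(n_per_hemi = 3) {
  region_set(data.frame(
    name = rep(sprintf("region%02d", seq_len(n_per_hemi)), 2),
    hemisphere = rep(c("left", "right"), each = n_per_hemi)))
}

toy_cohort <- function(n_per_group = c(12, 12), n_per_hemi = 3, seed = 1,
                       metric = "surface_area_mm2") {
  regions <- toy_regions(n_per_hemi)
  n <- sum(n_per_group)
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n * nrow(regions), log(2000), 0.3), n,
                 dimnames = list(NULL, regions$id))
  suppressWarnings(morph_cohort(
    subjects = sprintf("s%02d", seq_len(n)),
    group = rep(c("A", "B"), n_per_group),
    values = vals, regions = regions,
    age = round(stats::runif(n, 45, 80), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    metric = metric))
}

small_synthetic <- function(..., seed = 1) {
  suppressWarnings(generate_cohort(synthetic_spec(..., seed = seed)))
}

as_cov_network <- function(m, group = "A", n_subjects = 30) {
  ids <- sprintf("r%02d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  structure(list(matrix = m, group = group, n_subjects = n_subjects,
                 regions = data.frame(name = ids, hemisphere = "left",
                                      id = ids)),
            class = "cov_network")
}
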