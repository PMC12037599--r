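#' Pooled-variance two-sample t-test from summary statistics
#'
#' Reproduces a two-tailed unpaired t-test from printed group summaries
#' (mean, SD, n), using the pooled variance with `df = n1 + n2 - 2` — exactly
#' equivalent to running the data-level pooled t-test on any dataset with
#' those summaries.
#'
#' @param mean1,sd1,n1 first group summary
#' @param mean2,sd2,n2 second group summary
#' @return list with `statistic`, `df`, `p`
#' @export
summary_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean1 - mean2) / se
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Normality-gated two-group comparison
#'
#' Applies a Shapiro-Wilk test to each group at alpha = 0.05; if both groups
#' are compatible with normality the groups are compared with a pooled
#' two-tailed t-test, otherwise with a two-tailed Mann-Whitney U test (exact
#' for small untied samples, normal approximation with tie correction
#' otherwise). The gate can be overridden with `force`.
#'
#' @param values numeric vector
#' @param groups two-level factor, same length
#' @param force `"t_test"` or `"mann_whitney"` to bypass the gate
#' @param welch use Welch instead of pooled variance in the t branch
#' @return list with `variable` test used, `statistic`, `p`, `normal_p`
#'   (per-group Shapiro-Wilk p), and per-group `summary` (mean, sd, median,
#'   q1, q3, n)
#' @export
gated_group_test <- function(values, groups, force = NULL, welch = FALSE) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) != 2) stop("a group has no non-missing values")
  split_vals <- split(values, groups)
  if (any(lengths(split_vals) < 3)) stop("each group needs >= 3 values")
  normal_p <- vapply(split_vals, function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: not plausibly normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  test <- if (!is.null(force)) {
    match.arg(force, c("t_test", "mann_whitney"))
  } else if (all(normal_p > 0.05)) "t_test" else "mann_whitney"
  if (test == "t_test") {
    ht <- stats::t.test(split_vals[[1]], split_vals[[2]], var.equal = !welch)
  } else {
    n <- lengths(split_vals)
    has_ties <- anyDuplicated(values) > 0
    ht <- stats::wilcox.test(split_vals[[1]], split_vals[[2]],
                             exact = all(n <= 20) && !has_ties,
                             correct = TRUE)
  }
  summaries <- lapply(split_vals, function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(v), sd = stats::sd(v), q1 = q[1], median = q[2], q3 = q[3],
      n = length(v))
  })
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       normal_p = normal_p, summary = summaries)
}

#' Two-tailed p-value of a (partial) correlation coefficient
#'
#' Significance of a correlation `r` observed on `n` subjects after adjusting
#' for `k` covariates, via the t transform `t = r * sqrt(df / (1 - r^2))`
#' with `df = n - 2 - k`.
#'
#' @param r correlation coefficient
#' @param n number of observations
#' @param k number of adjusted covariates (0 for a plain Pearson r)
#' @return two-tailed p-value
#' @export
partial_r_pvalue <- function(r, n, k = 0) {
  df <- n - 2 - k
  if (df < 1) stop("not enough observations: df = ", df)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' Covariate-adjusted partial correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by OLS and
#' correlates the residuals. Significance uses the t transform
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` covariates.
#'
#' @param x,y numeric vectors
#' @param covariates numeric matrix or data.frame (n x k); `NULL` or empty
#'   reduces to the plain Pearson correlation
#' @return list with `r`, `p`, `statistic`, `df`, `n`, `k`
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    ok <- ok & stats::complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  df <- n - 2L - k
  if (df < 1) stop("not enough observations: df = ", df)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("singular covariate design")
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  r <- stats::cor(rx, ry)
  list(r = r, p = partial_r_pvalue(r, n, k),
       statistic = r * sqrt(df / (1 - r^2)), df = df, n = n, k = k)
}

#' Demographics/clinical comparison table for a cohort
#'
#' Runs [gated_group_test()] on age and every available clinical score and
#' tabulates the per-group summaries with the gated test's p-value — the
#' usual "Table 1" of a two-group study.
#'
#' @param cohort a [morph_cohort()]
#' @return data.frame, one row per variable
#' @export
clinical_table <- function(cohort) {
  vars <- c(list(age = cohort$age),
            if (!is.null(cohort$clinical)) as.list(cohort$clinical))
  rows <- lapply(names(vars), function(v) {
    res <- tryCatch(gated_group_test(vars[[v]], cohort$group),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    s1 <- res$summary[[1]]; s2 <- res$summary[[2]]
    data.frame(variable = v, test = res$test,
               mean_a = s1[["mean"]], sd_a = s1[["sd"]],
               median_a = s1[["median"]], n_a = s1[["n"]],
               mean_b = s2[["mean"]], sd_b = s2[["sd"]],
               median_b = s2[["median"]], n_b = s2[["n"]],
               statistic = res$statistic, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region-by-clinical partial correlations within one group
#'
#' For each requested region and clinical variable, the partial correlation
#' (adjusted for age and sex by default) between the regional morphometric and
#' the score, within one group's subjects. Reported uncorrected, as an
#' exploratory screen.
#'
#' @param cohort a [morph_cohort()] with clinical scores
#' @param group group level
#' @param regions region ids (default: all)
#' @param clinical_vars clinical column names (default: all available)
#' @param adjust covariates to adjust for (subset of `c("age", "sex")`)
#' @return data.frame: region, variable, r, p, n, df
#' @export
clinical_correlations <- function(cohort, group, regions = NULL,
                                  clinical_vars = NULL,
                                  adjust = c("age", "sex")) {
  if (is.null(cohort$clinical)) stop("cohort has no clinical scores")
  idx <- cohort$group == group
  if (is.null(regions)) regions <- cohort$regions$id
  if (is.null(clinical_vars)) clinical_vars <- names(cohort$clinical)
  covs <- NULL
  if (length(adjust) > 0) {
    covs <- cbind(if ("age" %in% adjust) data.frame(age = cohort$age[idx]),
                  if ("sex" %in% adjust)
                    data.frame(sexM = as.numeric(cohort$sex[idx] == "M")))
  }
  grid <- expand.grid(region = regions, variable = clinical_vars,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pc <- tryCatch(
      partial_correlation(cohort$values[idx, grid$region[i]],
                          cohort$clinical[idx, grid$variable[i]], covs),
      error = function(e) NULL)
    if (is.null(pc)) return(NULL)
    data.frame(group = group, region = grid$region[i],
               variable = grid$variable[i], r = pc$r, p = pc$p, n = pc$n,
               df = pc$df, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
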