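#' Remove nuisance covariate effects from regional morphometrics
#'
#' Fits, for each region independently, an ordinary least-squares model
#' `value ~ intercept + covariates` and replaces the values by the residuals.
#' By default the model is fitted on all subjects pooled across both groups,
#' so that group differences in covariance are not distorted by group-specific
#' centering; set `pooled = FALSE` to fit within each group.
#'
#' Residuals are not re-standardized: the downstream Pearson correlation is
#' scale-invariant, so standardization would be a no-op for the networks.
#'
#' @param cohort a [morph_cohort()]
#' @param covariates character vector drawn from `c("age", "sex")`; empty
#'   vector means intercept-only (grand-mean centering).
#' @param pooled fit on the pooled sample (default) or per group.
#' @return a corrected [morph_cohort()] (`corrected = TRUE`), with the fitted
#'   coefficient matrix attached as attribute `"adjustment"`.
#' @export
residualize <- function(cohort, covariates = c("age", "sex"), pooled = TRUE) {
  stopifnot(inherits(cohort, "morph_cohort"))
  if (!all(covariates %in% c("age", "sex"))) {
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, c("age", "sex")), collapse = ", "))
  }
  build_design <- function(idx) {
    X <- matrix(1, length(idx), 1, dimnames = list(NULL, "(Intercept)"))
    if ("age" %in% covariates) X <- cbind(X, age = cohort$age[idx])
    if ("sex" %in% covariates) {
      X <- cbind(X, sexM = as.numeric(cohort$sex[idx] == "M"))
    }
    X
  }
  fit_block <- function(idx) {
    X <- build_design(idx)
    if (qr(X)$rank < ncol(X)) {
      stop("singular covariate design (constant covariate column?)")
    }
    if (length(idx) <= ncol(X)) stop("fewer subjects than model parameters")
    fit <- stats::lm.fit(X, cohort$values[idx, , drop = FALSE])
    list(res = fit$residuals, coef = fit$coefficients)
  }
  resid <- cohort$values
  if (pooled) {
    f <- fit_block(seq_along(cohort$subjects))
    resid[, ] <- f$res
    coefs <- f$coef
  } else {
    coefs <- list()
    for (g in levels(cohort$group)) {
      idx <- which(cohort$group == g)
      f <- fit_block(idx)
      resid[idx, ] <- f$res
      coefs[[g]] <- f$coef
    }
  }
  out <- cohort
  out$values <- resid
  out$corrected <- TRUE
  attr(out, "adjustment") <- list(covariates = covariates, pooled = pooled,
                                  coefficients = coefs)
  out
}
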