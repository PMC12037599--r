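#' Specification for a synthetic two-group morphometric cohort
#'
#' Defines the generative model used in place of the (non-deposited) imaging
#' cohort: per group, subject latent vectors are drawn from a multivariate
#' normal with block-structured correlation — regions within a module
#' correlate at `r_in`, regions across modules at `r_out` — then diluted with
#' independent noise, given linear age and sex effects, and mapped onto
#' realistic regional mean/scale profiles (surface area in mm2 or thickness
#' in mm).
#'
#' `group_effect` multiplies the between-block correlations of group B only:
#' 1 is the null (both groups share one covariance); values below 1 fragment
#' group B's between-module integration, which lengthens shortest paths in
#' its thresholded network (higher normalized path length), emulating a
#' covariance-integration deficit.
#'
#' @param n_per_group two group sizes (default 50 and 49)
#' @param regions a [region_set()] (default the 68-region Desikan set)
#' @param n_blocks number of correlation modules; regions are split into
#'   contiguous blocks of near-equal size in canonical order (default 4)
#' @param r_in,r_out within- and between-block latent correlation
#'   (defaults 0.5 and 0.15)
#' @param group_effect multiplier on group B's between-block correlation
#'   (default 1 = null)
#' @param noise_sd SD of independent latent noise added on the unit-variance
#'   latent scale (default 0.3)
#' @param metric `"surface_area_mm2"` or `"thickness_mm"`; sets the regional
#'   mean range (500-10000 mm2 or 1.5-4.5 mm) and the default covariate
#'   effect sizes
#' @param age_slope,sex_offset per-region covariate effects as fractions of
#'   the regional mean: change per year of age, and male-minus-female offset
#' @param cv regional scale (SD of the latent contribution) as a fraction of
#'   the regional mean
#' @param clinical also generate plausible clinical scores (default TRUE)
#' @param seed master seed for everything the generator draws
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_per_group = c(50L, 49L),
                           regions = desikan_regions(),
                           n_blocks = 4L, r_in = 0.5, r_out = 0.15,
                           group_effect = 1.0, noise_sd = 0.3,
                           metric = c("surface_area_mm2", "thickness_mm"),
                           age_slope = NULL, sex_offset = NULL,
                           cv = NULL, clinical = TRUE, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 4),
            r_in >= 0, r_in < 1, r_out >= 0, r_out <= r_in,
            group_effect >= 0, noise_sd >= 0, n_blocks >= 1)
  if (is.null(age_slope)) {
    age_slope <- if (metric == "surface_area_mm2") -0.003 else -0.002
  }
  if (is.null(sex_offset)) {
    sex_offset <- if (metric == "surface_area_mm2") 0.08 else 0.01
  }
  if (is.null(cv)) cv <- if (metric == "surface_area_mm2") 0.10 else 0.05
  structure(list(n_per_group = as.integer(n_per_group), regions = regions,
                 n_blocks = as.integer(n_blocks), r_in = r_in, r_out = r_out,
                 group_effect = group_effect, noise_sd = noise_sd,
                 metric = metric, age_slope = age_slope,
                 sex_offset = sex_offset, cv = cv, clinical = clinical,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Contiguous near-equal block assignment of R regions into n_blocks modules.
block_assignment <- function(n_regions, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_regions))
}

# Block-structured latent correlation matrix; errors if not PSD.
block_correlation <- function(n_regions, blocks, r_in, r_out) {
  same <- outer(blocks, blocks, "==")
  S <- ifelse(same, r_in, r_out)
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("implied correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  }
  S
}

#' Generate a synthetic morphometric cohort
#'
#' Draws the cohort described by a [synthetic_spec()]: group A from the base
#' block-correlation structure, group B with its between-block correlations
#' multiplied by `group_effect`; adds independent latent noise, linear age
#' (uniform 45-80 years) and sex (Bernoulli 1/2) effects, and shifts/scales
#' every region onto its mean profile. Fully deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()]
#' @return a [morph_cohort()]; the generating spec is attached as attribute
#'   `"spec"`
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  R <- nrow(spec$regions)
  blocks <- block_assignment(R, spec$n_blocks)
  seeds <- derive_seeds(spec$seed, 6L)
  # fixed regional mean profile, reproducible from the seed
  set.seed(seeds[1])
  mu <- if (spec$metric == "surface_area_mm2") {
    stats::runif(R, 500, 10000)
  } else {
    stats::runif(R, 1.5, 4.5)
  }
  scale_r <- spec$cv * mu
  n_tot <- sum(spec$n_per_group)
  set.seed(seeds[2])
  age <- stats::runif(n_tot, 45, 80)
  sex <- ifelse(stats::runif(n_tot) < 0.5, "M", "F")
  group <- factor(rep(c("A", "B"), spec$n_per_group))
  values <- matrix(NA_real_, n_tot, R,
                   dimnames = list(NULL, spec$regions$id))
  for (gi in 1:2) {
    r_out_g <- if (gi == 2) spec$r_out * spec$group_effect else spec$r_out
    S <- block_correlation(R, blocks, spec$r_in, r_out_g)
    idx <- which(group == levels(group)[gi])
    set.seed(seeds[2 + gi])
    z <- MASS::mvrnorm(length(idx), mu = rep(0, R), Sigma = S)
    z <- z + stats::rnorm(length(z), sd = spec$noise_sd)
    lat <- z / sqrt(1 + spec$noise_sd^2)  # back to unit latent variance
    base <- rep(1, length(idx)) %o% mu
    values[idx, ] <- base + lat * (rep(1, length(idx)) %o% scale_r) +
      outer(age[idx] - 62.5, spec$age_slope * mu) +
      outer(as.numeric(sex[idx] == "M"), spec$sex_offset * mu)
  }
  if (any(values <= 0)) {
    values[values <= 0] <- min(values[values > 0])  # clip pathological draws
  }
  clinical <- NULL
  if (isTRUE(spec$clinical)) {
    set.seed(seeds[5])
    duration <- pmax(1, round(stats::rlnorm(n_tot, log(7), 0.45), 1))
    clinical <- data.frame(
      updrs3 = pmax(5, round(stats::rnorm(n_tot, 54, 13.5), 0)),
      mmse = pmin(30, pmax(15, round(stats::rnorm(n_tot, 26, 3)))),
      pdq39 = pmax(0, round(stats::rnorm(n_tot, 70, 27))),
      bdi = pmax(0, round(stats::rnorm(n_tot, 18.7, 10.4))),
      ledd = pmax(50, round(stats::rnorm(n_tot, 818, 351), 1)),
      onset_age = round(age - duration, 1),
      duration = duration,
      hoehn_yahr = sample(seq(1.5, 5, by = 0.5), n_tot, replace = TRUE,
                          prob = c(1, 2, 4, 6, 6, 4, 2, 1)))
  }
  out <- morph_cohort(subjects = sprintf("sub%03d", seq_len(n_tot)),
                      group = group, values = values, regions = spec$regions,
                      age = age, sex = sex, metric = spec$metric,
                      clinical = clinical)
  attr(out, "spec") <- spec
  out
}

#' Write a synthetic cohort as a reloadable fixture
#'
#' Emits the morphometric/metadata TSV pair consumed by [load_cohort()] plus
#' a JSON manifest recording the generating parameters and seed, so the
#' cohort can be regenerated or reloaded bit-for-bit.
#'
#' @param cohort a cohort from [generate_cohort()]
#' @param dir output directory
#' @param stem file-name stem
#' @return invisibly, the paths written (morph, meta, manifest)
#' @export
write_fixture <- function(cohort, dir, stem = "synthetic") {
  paths <- write_cohort(cohort, dir, stem)
  spec <- attr(cohort, "spec")
  manifest <- file.path(dir, paste0(stem, "_manifest.json"))
  ground_truth <- if (!is.null(spec)) {
    spec$regions <- NULL
    c(unclass(spec), list(n_regions = nrow(cohort$regions)))
  } else list(note = "cohort not generated by synthetic_spec")
  jsonlite::write_json(ground_truth, manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = manifest))
}
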