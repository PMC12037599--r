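CLINICAL_COLUMNS <- c("updrs3", "mmse", "pdq39", "bdi", "ledd",
                      "onset_age", "duration", "hoehn_yahr", "education")

#' Construct a morphometric cohort
#'
#' The central data container: one row per subject, one column per region of
#' the region set, plus group labels, covariates and optional clinical scores.
#'
#' @param subjects character vector of subject IDs (unique).
#' @param group factor or character with exactly two levels.
#' @param values numeric matrix, subjects x regions, strictly positive for raw
#'   morphometrics; column names must equal `regions$id`.
#' @param regions a [region_set()].
#' @param age,sex per-subject covariates; `sex` coded `"F"`/`"M"`.
#' @param metric `"surface_area_mm2"` or `"thickness_mm"`.
#' @param clinical optional data.frame of per-subject clinical scores
#'   (NA allowed); row order matches `subjects`.
#' @param corrected logical; `TRUE` once values have been residualized
#'   (residuals may be negative, so positivity is no longer enforced).
#' @return an object of class `morph_cohort`
#' @export
morph_cohort <- function(subjects, group, values, regions, age, sex,
                         metric = c("surface_area_mm2", "thickness_mm"),
                         clinical = NULL, corrected = FALSE) {
  metric <- match.arg(metric)
  subjects <- as.character(subjects)
  n <- length(subjects)
  if (anyDuplicated(subjects)) stop("duplicate subject IDs")
  values <- as.matrix(values)
  if (nrow(values) != n) stop("value matrix rows != number of subjects")
  if (!identical(colnames(values), regions$id)) {
    if (is.null(colnames(values)) || !setequal(colnames(values), regions$id)) {
      missing <- setdiff(regions$id, colnames(values))
      stop("value matrix columns do not cover the region set; missing: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    values <- values[, regions$id, drop = FALSE]
  }
  if (anyNA(values)) stop("missing morphometric values")
  if (!corrected && any(values <= 0)) {
    stop("non-positive morphometric value(s) in subjects: ",
         paste(utils::head(subjects[rowSums(values <= 0) > 0], 5), collapse = ", "))
  }
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two group levels required, got ", nlevels(group))
  sizes <- table(group)
  if (any(sizes < 4)) stop("each group needs >= 4 subjects; sizes: ",
                           paste(sizes, collapse = ", "))
  if (any(sizes < 30)) {
    warning("group size(s) below 30 (", paste(sizes, collapse = ", "),
            "): correlation estimates may be unstable")
  }
  sex <- toupper(as.character(sex))
  if (!all(sex %in% c("F", "M"))) stop("sex must be coded F/M")
  age <- as.numeric(age)
  if (length(age) != n || length(sex) != n) stop("covariate length != number of subjects")
  if (anyNA(age)) stop("missing age")
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    if (nrow(clinical) != n) stop("clinical rows != number of subjects")
  }
  rownames(values) <- subjects
  structure(list(subjects = subjects, group = group, values = values,
                 regions = regions, age = age, sex = sex, metric = metric,
                 clinical = clinical, corrected = corrected),
            class = "morph_cohort")
}

#' @export
print.morph_cohort <- function(x, ...) {
  cat("<morph_cohort> ", length(x$subjects), " subjects x ", nrow(x$regions),
      " regions [", x$metric, if (x$corrected) ", corrected" else "", "]\n",
      sep = "")
  print(table(group = x$group))
  invisible(x)
}

#' @export
dim.morph_cohort <- function(x) dim(x$values)

# Map input morphometric headers to canonical region ids. Accepts the
# FreeSurfer aparcstats2table dialect (lh_bankssts_area, rh_cuneus_thickness)
# and a plain dotted dialect (lh.bankssts); extra non-region columns such as
# eTIV or lh_WhiteSurfArea_area are dropped.
match_region_columns <- function(headers, regions) {
  canon <- function(h) {
    h2 <- gsub("\\.", "_", h)
    h2 <- sub("_(area|thickness|volume|meancurv)$", "", h2)
    h2
  }
  ids <- canon(headers)
  match(regions$id, ids)
}

detect_metric <- function(headers) {
  if (any(grepl("(_|\\.)thickness$", headers))) "thickness_mm" else "surface_area_mm2"
}

#' Load a cohort from morphometric and metadata TSV files
#'
#' The morphometric table is `aparcstats2table`-style: first column subject ID,
#' then one column per region (`lh_bankssts_area` or `lh.bankssts` naming,
#' auto-detected); extra columns (eTIV, white-surface totals) are ignored.
#' The metadata table has columns `subject`, `group`, `age`, `sex` and optional
#' clinical columns. Subjects present in only one file are dropped with a
#' warning (morph-only) or ignored (meta-only).
#'
#' @param morph_path,meta_path TSV paths.
#' @param regions a [region_set()]; default the packaged 68-region set.
#' @param metric override the metric kind auto-detected from headers.
#' @return a [morph_cohort()]
#' @export
load_cohort <- function(morph_path, meta_path, regions = desikan_regions(),
                        metric = NULL) {
  morph <- utils::read.delim(morph_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("subject", "group", "age", "sex") %in% names(meta))) {
    stop("metadata must have columns subject, group, age, sex")
  }
  headers <- names(morph)[-1]
  idx <- match_region_columns(headers, regions)
  if (anyNA(idx)) {
    stop("morphometric table is missing region column(s): ",
         paste(utils::head(regions$id[is.na(idx)], 5), collapse = ", "))
  }
  if (is.null(metric)) metric <- detect_metric(headers)
  subj <- as.character(morph[[1]])
  vals <- as.matrix(morph[, -1, drop = FALSE][, idx, drop = FALSE])
  colnames(vals) <- regions$id
  meta$subject <- as.character(meta$subject)
  keep <- subj %in% meta$subject
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " subject(s) without metadata: ",
            paste(utils::head(subj[!keep], 5), collapse = ", "))
  }
  subj <- subj[keep]
  vals <- vals[keep, , drop = FALSE]
  m <- meta[match(subj, meta$subject), ]
  clin_cols <- intersect(CLINICAL_COLUMNS, names(m))
  clinical <- if (length(clin_cols) > 0) m[, clin_cols, drop = FALSE] else NULL
  out <- morph_cohort(subjects = subj, group = m$group, values = vals,
                      regions = regions, age = m$age, sex = m$sex,
                      metric = metric, clinical = clinical)
  message("loaded cohort: ", paste(sprintf("%s=%d", levels(out$group),
                                           table(out$group)), collapse = ", "))
  out
}

#' Write a cohort back to the TSV pair consumed by [load_cohort()]
#'
#' @param cohort a [morph_cohort()]
#' @param dir output directory (created if needed)
#' @param stem file-name stem
#' @return invisibly, the two file paths written
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suffix <- if (cohort$metric == "thickness_mm") "thickness" else "area"
  morph <- data.frame(subject = cohort$subjects, check.names = FALSE)
  # %.17g round-trips IEEE doubles exactly, so reload is bit-for-bit
  vals <- matrix(sprintf("%.17g", cohort$values), nrow = nrow(cohort$values))
  colnames(vals) <- paste0(colnames(cohort$values), "_", suffix)
  morph <- cbind(morph, as.data.frame(vals, check.names = FALSE))
  meta <- data.frame(subject = cohort$subjects,
                     group = as.character(cohort$group),
                     age = sprintf("%.17g", cohort$age), sex = cohort$sex)
  if (!is.null(cohort$clinical)) meta <- cbind(meta, cohort$clinical)
  morph_path <- file.path(dir, paste0(stem, "_", suffix, ".tsv"))
  meta_path <- file.path(dir, paste0(stem, "_meta.tsv"))
  utils::write.table(morph, morph_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(morph = morph_path, meta = meta_path))
}

#' Extract one group's value matrix
#' @param cohort a [morph_cohort()]
#' @param group a group level
#' @return numeric matrix, subjects-in-group x regions
#' @export
group_values <- function(cohort, group) {
  group <- as.character(group)
  if (!group %in% levels(cohort$group)) {
    stop("unknown group '", group, "'; levels: ",
         paste(levels(cohort$group), collapse = ", "))
  }
  cohort$values[cohort$group == group, , drop = FALSE]
}
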