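# The core statistic: per-patient, per-site temporal variability as the
# coefficient of variation (CV) of longitudinal alpha-diversity values and
# of within-patient UniFrac distances, plus the quartile-based
# stable/average/variable classification.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Defined for two or more values with a strictly positive mean; with
#' exactly two values the estimate is legal but low-confidence (see
#' `min_samples` in [build_profiles()]).
#'
#' @param values numeric vector, length >= 2, mean > 0.
#' @return A non-negative number.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    mv_insufficient_data("CV requires at least 2 non-missing values")
  m <- mean(values)
  if (m <= 0)
    mv_domain_error("CV undefined for non-positive mean")
  sd(values) / m
}

site_samples <- function(meta, patient, site) {
  s <- meta$samples
  s <- s[s$patient_id == patient & s$site == site, , drop = FALSE]
  s[order(s$order), , drop = FALSE]
}

#' CV of a patient-site's alpha-diversity series
#'
#' @param alpha an [alpha_table()] data.frame.
#' @param meta a [cohort_metadata()].
#' @param patient,site patient id and body site.
#' @param metric `"shannon"`, `"simpson"` or `"chao1"`.
#' @param min_samples minimum longitudinal samples required (default 3).
#' @return The CV (sample order is irrelevant).
#' @export
alpha_cv <- function(alpha, meta, patient, site,
                     metric = c("shannon", "simpson", "chao1"),
                     min_samples = 3L) {
  metric <- match.arg(metric)
  ids <- intersect(site_samples(meta, patient, site)$sample_id,
                   alpha$sample_id)
  if (length(ids) < min_samples)
    mv_insufficient_data(sprintf(
      "patient '%s' has %d %s sample(s); %d required",
      patient, length(ids), site, min_samples))
  coefficient_of_variation(alpha[[metric]][match(ids, alpha$sample_id)])
}

#' CV of a patient-site's within-patient UniFrac distances
#'
#' The distance multiset is either all unordered within-patient pairs
#' (default: uses all information and is robust to collection order) or
#' only consecutive-by-order pairs.
#'
#' @param dm a [distance_matrix()] containing the patient's samples.
#' @param meta a [cohort_metadata()].
#' @param patient,site patient id and body site.
#' @param pair_mode `"all_pairs"` or `"consecutive"`.
#' @param min_samples minimum longitudinal samples required (default 3).
#' @return The CV of the selected distances.
#' @export
beta_cv <- function(dm, meta, patient, site,
                    pair_mode = c("all_pairs", "consecutive"),
                    min_samples = 3L) {
  pair_mode <- match.arg(pair_mode)
  ids <- intersect(site_samples(meta, patient, site)$sample_id, rownames(dm))
  if (length(ids) < min_samples)
    mv_insufficient_data(sprintf(
      "patient '%s' has %d %s sample(s); %d required",
      patient, length(ids), site, min_samples))
  sub <- dm[ids, ids, drop = FALSE]
  dists <- if (pair_mode == "all_pairs") {
    sub[upper.tri(sub)]
  } else {
    sub[cbind(seq_len(length(ids) - 1L), seq_len(length(ids) - 1L) + 1L)]
  }
  coefficient_of_variation(dists)
}

#' Per-patient, per-site variability profiles
#'
#' One row per (patient, site) with at least `min_samples` samples:
#' sample count and the CVs of Shannon, Simpson, Chao-1, and the
#' unweighted/weighted UniFrac distance sets. A CV that is undefined for a
#' patient (e.g. zero mean distance) is `NA`; skipped patient-sites are
#' recorded in the `skipped` attribute with a reason.
#'
#' @param alpha an [alpha_table()] data.frame.
#' @param dms named list with `uu` and `wu` [distance_matrix()] entries.
#' @param meta a [cohort_metadata()].
#' @param pair_mode,min_samples see [beta_cv()].
#' @return data.frame of class `variability_profiles` with columns
#'   `patient_id`, `site`, `n_samples`, `cv_shannon`, `cv_simpson`,
#'   `cv_chao1`, `cv_uu`, `cv_wu`.
#' @export
build_profiles <- function(alpha, dms, meta,
                           pair_mode = c("all_pairs", "consecutive"),
                           min_samples = 3L) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(inherits(meta, "cohort_metadata"))
  rows <- list()
  skipped <- list()
  quiet_cv <- function(expr) tryCatch(expr, microvar_error = function(e) NA_real_)
  for (patient in unique(meta$samples$patient_id)) {
    for (site in SITE_LEVELS) {
      ids <- intersect(site_samples(meta, patient, site)$sample_id,
                       alpha$sample_id)
      if (length(ids) == 0L) next
      if (length(ids) < min_samples) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          patient_id = patient, site = site,
          reason = sprintf("%d sample(s) < min_samples = %d",
                           length(ids), min_samples))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient, site = site, n_samples = length(ids),
        cv_shannon = quiet_cv(alpha_cv(alpha, meta, patient, site, "shannon", min_samples)),
        cv_simpson = quiet_cv(alpha_cv(alpha, meta, patient, site, "simpson", min_samples)),
        cv_chao1 = quiet_cv(alpha_cv(alpha, meta, patient, site, "chao1", min_samples)),
        cv_uu = quiet_cv(beta_cv(dms$uu, meta, patient, site, pair_mode, min_samples)),
        cv_wu = quiet_cv(beta_cv(dms$wu, meta, patient, site, pair_mode, min_samples)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), site = character(0),
               n_samples = integer(0), cv_shannon = numeric(0),
               cv_simpson = numeric(0), cv_chao1 = numeric(0),
               cv_uu = numeric(0), cv_wu = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(out) <- c("variability_profiles", "data.frame")
  out
}

CV_MEASURES <- c("cv_shannon", "cv_simpson", "cv_chao1", "cv_uu", "cv_wu")

#' Quartile stability categories
#'
#' Per body site (never pooled across sites), the cohort's CVs for one
#' measure are split at the first and third quartiles (linear-interpolation
#' quantiles): CV <= Q1 is `stable`, CV >= Q3 is `variable`, the middle two
#' quartiles are `average`. If Q1 = Q3 every patient is `average`.
#'
#' @param profiles a [build_profiles()] data.frame.
#' @param measure one of `cv_shannon`, `cv_simpson`, `cv_chao1`, `cv_uu`,
#'   `cv_wu`.
#' @return data.frame with columns `patient_id`, `site`, `measure`,
#'   `category`.
#' @export
categorize <- function(profiles, measure = CV_MEASURES) {
  measure <- match.arg(measure)
  out <- lapply(intersect(SITE_LEVELS, unique(profiles$site)), function(site) {
    p <- profiles[profiles$site == site & !is.na(profiles[[measure]]), ,
                  drop = FALSE]
    if (nrow(p) < 4L)
      mv_insufficient_data(sprintf(
        "site '%s' has %d profile(s) with %s; >= 4 required for quartiles",
        site, nrow(p), measure))
    cv <- p[[measure]]
    q <- quantile(cv, c(0.25, 0.75), type = 7, names = FALSE)
    category <- rep("average", length(cv))
    if (q[1] < q[2]) {
      category[cv <= q[1]] <- "stable"
      category[cv >= q[2]] <- "variable"
    }
    data.frame(patient_id = p$patient_id, site = site, measure = measure,
               category = category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-site correlation of a variability measure
#'
#' Pearson correlation between a patient's oral and stool CVs, over
#' patients profiled at both sites, with the two-sided p-value from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param profiles a [build_profiles()] data.frame.
#' @param measure a CV measure name.
#' @return list with `r`, `p` and `n` (number of paired patients).
#' @export
cross_site_correlation <- function(profiles, measure = CV_MEASURES) {
  measure <- match.arg(measure)
  oral <- profiles[profiles$site == "oral", c("patient_id", measure)]
  stool <- profiles[profiles$site == "stool", c("patient_id", measure)]
  merged <- merge(oral, stool, by = "patient_id", suffixes = c("_oral", "_stool"))
  merged <- merged[complete.cases(merged), , drop = FALSE]
  if (nrow(merged) < 3L)
    mv_insufficient_data("fewer than 3 patients profiled at both sites")
  ct <- pearson(merged[[paste0(measure, "_oral")]],
                merged[[paste0(measure, "_stool")]])
  list(r = ct$r, p = ct$p, n = nrow(merged))
}
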