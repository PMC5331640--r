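# Statistical screens linking variability to genera, outcomes and clinical
# covariates. The elementary tests (Pearson, Kruskal-Wallis, Welch t,
# Mann-Whitney U, Benjamini-Hochberg, OLS) are implemented here from their
# closed forms so that the test suite can check them against base R as an
# independent oracle. Each screen adjusts p-values within its own family
# (one screen x site x measure), never pooled across screens.

#' Pearson product-moment correlation with two-sided p
#'
#' p is derived from \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of
#' freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3, both non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) mv_insufficient_data("Pearson correlation requires n >= 3")
  if (var(x) == 0 || var(y) == 0)
    mv_domain_error("Pearson correlation undefined for constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: sort, multiply by m/rank, take the cumulative minimum
#' from the largest rank down, cap at 1; input order is preserved.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    mv_validation_error("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(m / seq_len(m) * p[o]))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Kruskal-Wallis rank test
#'
#' Midrank-based H with tie correction; p from a chi-square with k - 1
#' degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    mv_validation_error("kruskal_wallis requires at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) mv_validation_error("empty group")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3L) mv_insufficient_data("kruskal_wallis requires total n >= 3")
  r <- rank(x)
  g <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, g, sum)
  H <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) H <- H / tie_corr
  df <- length(groups) - 1L
  list(H = H, p = pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param a,b numeric vectors, each of length >= 2, at least one
#'   non-constant.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    mv_insufficient_data("welch_t requires >= 2 values per group")
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  if (va + vb == 0) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Mann-Whitney U test
#'
#' U is the smaller of the two placement counts. The p-value is two-sided:
#' exact (full enumeration of rank splits) when the combined n is at most
#' `exact_max` and there are no ties, otherwise a normal approximation with
#' tie correction and continuity correction.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact_max combined-size cutoff for the exact distribution
#'   (default 16).
#' @return list with `U`, `p`, `exact` (logical).
#' @export
mann_whitney <- function(a, b, exact_max = 16L) {
  if (length(a) == 0L || length(b) == 0L)
    mv_validation_error("mann_whitney requires non-empty groups")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (n <= exact_max && !has_ties) {
    # enumerate all C(n, na) assignments of ranks to group a
    splits <- combn(n, na)
    u_dist <- colSums(splits) - na * (na + 1) / 2
    p <- min(1, 2 * mean(u_dist <= u))
    return(list(U = u, p = p, exact = TRUE))
  }
  mu <- na * nb / 2
  ties <- table(c(a, b))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  if (sigma == 0) return(list(U = u, p = 1, exact = FALSE))
  z <- (u - mu + 0.5) / sigma
  list(U = u, p = min(1, 2 * pnorm(z)), exact = FALSE)
}

#' Column-normalize a count table to relative abundances
#'
#' @param table a [feature_table()] (zero-total samples must already be
#'   dropped, e.g. via [alpha_table()]/[beta_matrix()] preprocessing).
#' @return Numeric matrix (taxa x samples) whose columns each sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- colSums(table$counts)
  if (any(totals == 0))
    mv_domain_error(sprintf("zero-total sample '%s'; drop empty samples first",
                            colnames(table$counts)[totals == 0][1L]))
  sweep(table$counts, 2L, totals, "/")
}

#' Aggregate a feature table to genus level
#'
#' Sums counts of taxa sharing a genus label; `"unclassified"` is kept as
#' its own bucket. Per-sample totals are preserved.
#'
#' @param table a [feature_table()].
#' @return A genus-level [feature_table()] (taxon ids are genus labels).
#' @export
aggregate_genus <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  genus <- factor(table$taxonomy, levels = unique(table$taxonomy))
  agg <- rowsum(table$counts, genus, reorder = FALSE)
  feature_table(agg, setNames(rownames(agg), rownames(agg)))
}

association_result <- function(feature, statistic_name, statistic, p_raw,
                               n, p_adj = NULL, extra = NULL) {
  out <- data.frame(feature = feature, statistic_name = statistic_name,
                    statistic = statistic, p_raw = p_raw,
                    p_adj = if (is.null(p_adj)) benjamini_hochberg(p_raw) else p_adj,
                    n = n, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  class(out) <- c("association_result", "data.frame")
  out
}

# Genus-level relative abundance matrix restricted to one site's samples
# whose patients carry a profile; applies the cohort-wide mean-abundance
# inclusion filter (default 1%).
screen_abundances <- function(genus_rel, profiles, meta, site, min_abundance) {
  s <- meta$samples
  keep <- s$sample_id[s$site == site &
                        s$patient_id %in% profiles$patient_id[profiles$site == site]]
  keep <- intersect(colnames(genus_rel), keep)
  if (length(keep) == 0L)
    mv_insufficient_data(sprintf("no profiled samples at site '%s'", site))
  rel <- genus_rel[, keep, drop = FALSE]
  rel[rowMeans(rel) >= min_abundance, , drop = FALSE]
}

#' Genus abundance vs. temporal-variability correlation screen
#'
#' For each genus passing the cohort-wide mean relative-abundance filter,
#' the Pearson correlation between its relative abundance and the patient's
#' CV for `measure` at `site`. At the default `level = "sample"` every
#' sample carries its patient's CV (each sample is one observation, as in a
#' per-sample heatmap); `level = "patient_mean"` first averages abundance
#' per patient. p-values are BH-adjusted across genera and rows are sorted
#' by decreasing r.
#'
#' @param genus_rel genus x sample relative-abundance matrix (from
#'   [relative_abundance()] of [aggregate_genus()] output).
#' @param profiles a [build_profiles()] data.frame.
#' @param meta a [cohort_metadata()].
#' @param measure a CV measure name (e.g. `"cv_wu"`).
#' @param site `"oral"` or `"stool"`.
#' @param level `"sample"` (default) or `"patient_mean"`.
#' @param min_abundance genus inclusion threshold on cohort-wide mean
#'   relative abundance (default 0.01).
#' @return An `association_result` data.frame (one row per genus).
#' @export
genus_cv_correlation <- function(genus_rel, profiles, meta,
                                 measure = CV_MEASURES,
                                 site = SITE_LEVELS,
                                 level = c("sample", "patient_mean"),
                                 min_abundance = 0.01) {
  measure <- match.arg(measure)
  site <- match.arg(site)
  level <- match.arg(level)
  rel <- screen_abundances(genus_rel, profiles, meta, site, min_abundance)
  if (nrow(rel) == 0L) {
    warning("no genera pass the abundance filter", call. = FALSE)
    return(association_result(character(0), character(0), numeric(0),
                              numeric(0), integer(0)))
  }
  prof <- profiles[profiles$site == site, c("patient_id", measure)]
  cv_of <- setNames(prof[[measure]], prof$patient_id)
  pat <- meta$samples$patient_id[match(colnames(rel), meta$samples$sample_id)]
  if (level == "patient_mean") {
    by_pat <- sapply(split(seq_along(pat), pat), function(ix)
      rowMeans(rel[, ix, drop = FALSE]))
    if (is.null(dim(by_pat)))
      by_pat <- matrix(by_pat, nrow = 1L,
                       dimnames = list(rownames(rel), names(by_pat)))
    rel <- by_pat
    y <- cv_of[colnames(rel)]
  } else {
    y <- cv_of[pat]
  }
  keep <- !is.na(y)
  rel <- rel[, keep, drop = FALSE]
  y <- y[keep]
  const <- apply(rel, 1L, function(x) var(x) == 0)
  if (any(const)) {
    warning(sprintf("excluding %d constant genus/genera: %s", sum(const),
                    paste(rownames(rel)[const], collapse = ", ")),
            call. = FALSE)
    rel <- rel[!const, , drop = FALSE]
  }
  if (nrow(rel) == 0L)
    return(association_result(character(0), character(0), numeric(0),
                              numeric(0), integer(0)))
  stats_ <- apply(rel, 1L, function(x) unlist(pearson(x, y)[c("r", "p")]))
  res <- association_result(rownames(rel), "pearson_r", stats_["r", ],
                            stats_["p", ], length(y))
  res[order(-res$statistic), , drop = FALSE]
}

significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Genus abundance across stability categories (Kruskal-Wallis screen)
#'
#' Abundance is summarized per patient (mean of the patient's sample
#' relative abundances at the site) because stability categories are
#' patient-level; each genus is then tested across the stable / average /
#' variable groups with Kruskal-Wallis and BH-adjusted across genera.
#' Significance stars mark adjusted p at 0.05 / 0.01 / 0.001.
#'
#' @inheritParams genus_cv_correlation
#' @param assignments output of [categorize()] for `site`'s cohort.
#' @return An `association_result` data.frame with a `stars` column and
#'   per-category median abundances.
#' @export
genus_category_tests <- function(genus_rel, assignments, meta,
                                 site = SITE_LEVELS, min_abundance = 0.01) {
  site <- match.arg(site)
  asg <- assignments[assignments$site == site, , drop = FALSE]
  if (nrow(asg) == 0L) mv_insufficient_data(sprintf("no assignments for site '%s'", site))
  cats <- c("stable", "average", "variable")
  if (!all(cats %in% asg$category))
    mv_validation_error(paste(
      "empty stability category at site", site,
      "- the cohort is too small or too uniform for quartile categories"))
  fake_profiles <- data.frame(patient_id = asg$patient_id, site = site)
  rel <- screen_abundances(genus_rel, fake_profiles, meta, site, min_abundance)
  if (nrow(rel) == 0L) {
    warning("no genera pass the abundance filter", call. = FALSE)
    return(association_result(character(0), character(0), numeric(0),
                              numeric(0), integer(0)))
  }
  pat <- meta$samples$patient_id[match(colnames(rel), meta$samples$sample_id)]
  per_patient <- sapply(split(seq_along(pat), pat), function(ix)
    rowMeans(rel[, ix, drop = FALSE]))
  if (is.null(dim(per_patient)))
    per_patient <- matrix(per_patient, nrow = 1L,
                          dimnames = list(rownames(rel), names(per_patient)))
  cat_of <- setNames(asg$category, asg$patient_id)[colnames(per_patient)]
  res_rows <- lapply(rownames(per_patient), function(g) {
    groups <- split(per_patient[g, ], factor(cat_of, levels = cats))
    kw <- kruskal_wallis(groups)
    meds <- vapply(groups, stats::median, numeric(1L))
    data.frame(feature = g, statistic_name = "kruskal_H", statistic = kw$H,
               p_raw = kw$p, n = ncol(per_patient),
               median_stable = meds[["stable"]],
               median_average = meds[["average"]],
               median_variable = meds[["variable"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res_rows)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res$stars <- significance_stars(res$p_adj)
  res <- res[c("feature", "statistic_name", "statistic", "p_raw", "p_adj",
               "n", "median_stable", "median_average", "median_variable",
               "stars")]
  res <- res[order(res$p_adj, res$p_raw), , drop = FALSE]
  class(res) <- c("association_result", "data.frame")
  res
}

OUTCOMES <- c("infection_during_ic_any", "infection_during_ic_mdi",
              "infection_90d_post", "remission")

outcome_groups <- function(meta, outcome) {
  p <- meta$patients
  flag <- switch(outcome,
                 infection_during_ic_any = p$infection_during_ic != "none",
                 infection_during_ic_mdi = p$infection_during_ic == "MDI",
                 infection_90d_post = as.logical(p$infection_90d_post),
                 remission = as.logical(p$remission),
                 mv_validation_error(sprintf("unknown outcome '%s'", outcome)))
  if (anyNA(flag))
    mv_validation_error(sprintf(
      "missing outcome '%s' for patient(s): %s", outcome,
      paste(p$patient_id[is.na(flag)], collapse = ", ")))
  setNames(flag, p$patient_id)
}

#' Compare temporal variability between clinical outcome groups
#'
#' Welch's t test on a CV measure between patients with and without the
#' outcome (infection during induction chemotherapy — pooled or
#' microbiologically-documented only — infection within 90 days post
#' recovery, or leukemia remission).
#'
#' @param profiles a [build_profiles()] data.frame.
#' @param meta a [cohort_metadata()].
#' @param outcome one of `"infection_during_ic_any"`,
#'   `"infection_during_ic_mdi"`, `"infection_90d_post"`, `"remission"`.
#' @param measure a CV measure name.
#' @param site `"oral"` or `"stool"`.
#' @return An `association_result` row with group means and sizes.
#' @export
outcome_comparisons <- function(profiles, meta, outcome = OUTCOMES,
                                measure = CV_MEASURES, site = SITE_LEVELS) {
  outcome <- match.arg(outcome)
  measure <- match.arg(measure)
  site <- match.arg(site)
  flag <- outcome_groups(meta, outcome)
  prof <- profiles[profiles$site == site & !is.na(profiles[[measure]]), ]
  cv <- setNames(prof[[measure]], prof$patient_id)
  yes <- cv[names(cv)[flag[names(cv)]]]
  no <- cv[names(cv)[!flag[names(cv)]]]
  if (length(yes) < 2L || length(no) < 2L)
    mv_insufficient_data(sprintf(
      "outcome '%s' at site '%s': groups of size %d and %d (need >= 2 each)",
      outcome, site, length(yes), length(no)))
  wt <- welch_t(yes, no)
  association_result(
    feature = sprintf("%s:%s:%s", outcome, site, measure),
    statistic_name = "welch_t", statistic = wt$t, p_raw = wt$p,
    p_adj = wt$p, n = length(yes) + length(no),
    extra = data.frame(mean_with = mean(yes), mean_without = mean(no),
                       n_with = length(yes), n_without = length(no),
                       df = wt$df))
}

#' Genus abundance vs. outcome screen (Mann-Whitney)
#'
#' Per genus passing the abundance filter: Mann-Whitney U between per-
#' patient mean relative abundances of patients with and without the
#' outcome, BH-adjusted across genera.
#'
#' @inheritParams outcome_comparisons
#' @param genus_rel genus x sample relative-abundance matrix.
#' @param min_abundance genus inclusion threshold (default 0.01).
#' @return An `association_result` data.frame.
#' @export
genus_outcome_tests <- function(genus_rel, meta, outcome = OUTCOMES,
                                site = SITE_LEVELS, min_abundance = 0.01) {
  outcome <- match.arg(outcome)
  site <- match.arg(site)
  flag <- outcome_groups(meta, outcome)
  all_prof <- data.frame(patient_id = names(flag), site = site)
  rel <- screen_abundances(genus_rel, all_prof, meta, site, min_abundance)
  pat <- meta$samples$patient_id[match(colnames(rel), meta$samples$sample_id)]
  per_patient <- sapply(split(seq_along(pat), pat), function(ix)
    rowMeans(rel[, ix, drop = FALSE]))
  if (is.null(dim(per_patient)))
    per_patient <- matrix(per_patient, nrow = 1L,
                          dimnames = list(rownames(rel), names(per_patient)))
  grp <- flag[colnames(per_patient)]
  if (sum(grp) == 0L || sum(!grp) == 0L)
    mv_insufficient_data("all patients fall in one outcome group")
  rows <- lapply(rownames(per_patient), function(g) {
    mw <- mann_whitney(per_patient[g, grp], per_patient[g, !grp])
    data.frame(feature = g, statistic_name = "mannwhitney_U",
               statistic = mw$U, p_raw = mw$p, n = length(grp),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res <- res[c("feature", "statistic_name", "statistic", "p_raw", "p_adj", "n")]
  res <- res[order(res$p_raw), , drop = FALSE]
  class(res) <- c("association_result", "data.frame")
  res
}

REGRESSION_COVARIATES <- c("age", "pip_tazo_gt72h", "cefepime_gt72h",
                           "carbapenem_gt72h", "days_all_abx",
                           "days_treatment_abx", "n_antibiotics",
                           "chemo_non_flu_high_intensity",
                           "chemo_hypomethylator")

regression_design <- function(meta, patient_ids) {
  p <- meta$patients[match(patient_ids, meta$patients$patient_id), ]
  X <- cbind(
    `(Intercept)` = 1,
    age = as.numeric(p$age),
    pip_tazo_gt72h = as.numeric(p$pip_tazo_gt72h),
    cefepime_gt72h = as.numeric(p$cefepime_gt72h),
    carbapenem_gt72h = as.numeric(p$carbapenem_gt72h),
    days_all_abx = as.numeric(p$days_all_abx),
    days_treatment_abx = as.numeric(p$days_treatment_abx),
    n_antibiotics = as.numeric(p$n_antibiotics),
    chemo_non_flu_high_intensity =
      as.numeric(p$chemo_category == "non_fludarabine_high_intensity"),
    chemo_hypomethylator = as.numeric(p$chemo_category == "hypomethylator"))
  if (anyNA(X)) {
    bad <- patient_ids[rowSums(is.na(X)) > 0]
    mv_validation_error(sprintf(
      "missing covariate value(s) for patient(s): %s",
      paste(bad, collapse = ", ")))
  }
  rownames(X) <- patient_ids
  X
}

ols_fit <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    mv_insufficient_data(sprintf("OLS needs n > %d covariates; n = %d", p, n))
  qr_ <- qr(X)
  if (qr_$rank < p) {
    collinear <- colnames(X)[qr_$pivot[(qr_$rank + 1L):p]]
    mv_validation_error(sprintf("rank-deficient design; collinear column(s): %s",
                                paste(collinear, collapse = ", ")))
  }
  coef <- qr.coef(qr_, y)
  res <- y - drop(X %*% coef)
  df <- n - p
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tstat <- coef / se
  data.frame(term = colnames(X), estimate = unname(coef), se = unname(se),
             t = unname(tstat),
             p = 2 * pt(-abs(unname(tstat)), df),
             stringsAsFactors = FALSE)
}

#' Multivariable OLS of a variability measure on clinical covariates
#'
#' Ordinary least squares with intercept of one CV measure at one site on
#' the fixed clinical covariate set: age, the three >72h antibiotic
#' indicators, days on all / treatment antibiotics, number of antibiotics,
#' and two chemotherapy-regimen indicators (non-fludarabine high intensity,
#' hypomethylator) with fludarabine-containing (and "other") as the
#' reference. Two-sided t tests on each coefficient.
#'
#' @param profiles a [build_profiles()] data.frame.
#' @param meta a [cohort_metadata()].
#' @param response a CV measure name.
#' @param site `"oral"` or `"stool"`.
#' @return data.frame of class `regression_result`: one row per term with
#'   `estimate`, `se`, `t`, `p`.
#' @export
multivariable_ols <- function(profiles, meta, response = CV_MEASURES,
                              site = SITE_LEVELS) {
  response <- match.arg(response)
  site <- match.arg(site)
  prof <- profiles[profiles$site == site & !is.na(profiles[[response]]), ]
  if (nrow(prof) == 0L)
    mv_insufficient_data(sprintf("no %s profiles at site '%s'", response, site))
  X <- regression_design(meta, prof$patient_id)
  fit <- ols_fit(X, prof[[response]])
  fit$response <- response
  fit$site <- site
  fit$n <- nrow(X)
  class(fit) <- c("regression_result", "data.frame")
  fit
}

#' Covariate p-value grid across sites and measures
#'
#' Runs [multivariable_ols()] for every combination of site (oral, stool)
#' and measure (`cv_shannon`, `cv_uu`, `cv_wu`) and returns the 9 x 6 grid
#' of coefficient p-values (covariates x site-measure columns).
#'
#' @param profiles,meta as in [multivariable_ols()].
#' @return Numeric matrix, rows = covariates, columns like `oral.cv_shannon`.
#' @export
multivariable_grid <- function(profiles, meta) {
  measures <- c("cv_shannon", "cv_uu", "cv_wu")
  cols <- list()
  for (site in SITE_LEVELS) {
    for (m in measures) {
      fit <- multivariable_ols(profiles, meta, m, site)
      cols[[paste(site, m, sep = ".")]] <-
        setNames(fit$p, fit$term)[REGRESSION_COVARIATES]
    }
  }
  do.call(cbind, cols)
}
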