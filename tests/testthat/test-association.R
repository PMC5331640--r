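test_that("pearson matches the closed form and base R", {
  expect_equal(pearson(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson(1:3, c(3, 2, 1))$r, -1)
  res <- pearson(1:4, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  ct <- cor.test(1:4, c(1, 3, 2, 4))
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  expect_error(pearson(c(1, 1, 1), 1:3), class = "mv_domain_error")
})

test_that("benjamini_hochberg matches the step-up procedure", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03)),
               c(0.03, 0.04, 0.04))
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "mv_validation_error")
})

test_that("benjamini_hochberg agrees with p.adjust on random ladders", {
  set.seed(51)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone in the input ranks
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("kruskal_wallis matches hand values and stats::kruskal.test", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-10)
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)
  expect_equal(kruskal_wallis(list(c(1, 4), c(2, 3)))$H, 0)
  expect_error(kruskal_wallis(list(1:3)), class = "mv_validation_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0))),
               class = "mv_validation_error")
  set.seed(52)
  for (rep in 1:10) {
    g <- lapply(1:3, function(i) sample(1:20, sample(3:8, 1), replace = TRUE))
    ref <- kruskal.test(g)
    mine <- kruskal_wallis(g)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t matches hand values and stats::t.test", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(welch_t(1:5, 1:5)$t, 0)
  expect_equal(welch_t(1:5, 1:5)$p, 1)
  swap <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)
  set.seed(53)
  for (rep in 1:10) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), 1, 2)
    ref <- t.test(a, b)
    mine <- welch_t(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("mann_whitney exact and approximate branches match references", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_true(res$exact)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  # pair counting: only 3 > 2, so U_a = 1, U_b = 3, U = min = 1 (matches
  # stats::wilcox.test's W for the first sample)
  expect_equal(mann_whitney(c(1, 3), c(2, 4))$U, 1)
  expect_equal(mann_whitney(c(1, 3), c(2, 4))$U,
               unname(wilcox.test(c(1, 3), c(2, 4))$statistic))
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$U, 9 / 2)
  expect_error(mann_whitney(numeric(0), 1:3), class = "mv_validation_error")
  set.seed(54)
  for (rep in 1:10) {
    a <- sample(1:100, 6); b <- sample(101:200, 5) - sample(0:120, 5)
    if (anyDuplicated(c(a, b))) next
    ref <- wilcox.test(a, b, exact = TRUE)
    mine <- mann_whitney(a, b)
    # wilcox.test W is U of the first sample
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  # large-sample branch against the normal approximation in base R
  a <- rnorm(20); b <- rnorm(25, 0.5)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mann_whitney(a, b)$p, ref$p.value, tolerance = 1e-8)
})

test_that("KW with two groups agrees in rejection with Mann-Whitney", {
  set.seed(55)
  for (rep in 1:20) {
    a <- rnorm(8); b <- rnorm(9, sample(c(0, 2), 1))
    kw <- kruskal_wallis(list(a, b))
    mw <- mann_whitney(a, b, exact_max = 0L)  # force same asymptotic regime
    expect_equal(kw$p < 0.05, mw$p < 0.05)
  }
})

test_that("relative abundance and genus aggregation conserve totals", {
  counts <- matrix(c(2L, 3L, 0L, 0L, 5L, 2L), nrow = 3,
                   dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  ft <- feature_table(counts, c(t1 = "G", t2 = "G", t3 = "H"))
  rel <- relative_abundance(ft)
  expect_equal(colSums(rel), c(s1 = 1, s2 = 1), tolerance = 1e-12)
  agg <- aggregate_genus(ft)
  expect_equal(agg$counts["G", ], c(s1 = 5L, s2 = 5L))
  expect_equal(colSums(agg$counts), colSums(counts))
  expect_equal(rel["t1", "s1"], 0.4)
})

test_that("multivariable OLS recovers exact linear signals and flags rank loss", {
  meta <- small_cohort(seed = 71L, n_patients = 20L)$meta
  X <- microvar:::regression_design(meta, meta$patients$patient_id)
  y <- drop(0.3 + 0.01 * X[, "days_all_abx"])
  prof <- data.frame(patient_id = rownames(X), site = "oral",
                     cv_shannon = y)
  fit <- multivariable_ols(prof, meta, "cv_shannon", "oral")
  expect_equal(fit$estimate[fit$term == "days_all_abx"], 0.01,
               tolerance = 1e-10)
  expect_equal(fit$estimate[fit$term == "(Intercept)"], 0.3,
               tolerance = 1e-10)
  others <- setdiff(fit$term, c("days_all_abx", "(Intercept)"))
  expect_true(all(abs(fit$estimate[fit$term %in% others]) < 1e-10))

  # duplicate covariate -> rank deficiency naming the column
  expect_error(microvar:::ols_fit(cbind(X, dup = X[, "age"]), y),
               "dup", class = "mv_validation_error")
  # agreement with lm on a noisy response
  set.seed(56)
  y2 <- y + rnorm(length(y), 0, 0.05)
  prof$cv_shannon <- y2
  fit2 <- multivariable_ols(prof, meta, "cv_shannon", "oral")
  ref <- summary(lm(y2 ~ X - 1))$coefficients
  expect_equal(fit2$estimate, unname(ref[, 1]), tolerance = 1e-8)
  expect_equal(fit2$p, unname(ref[, 4]), tolerance = 1e-8)
})

test_that("OLS errors on missing covariates, naming patients", {
  meta <- tiny_meta()
  meta$patients$age[2] <- NA
  prof <- data.frame(patient_id = c("P1", "P2"), site = "oral",
                     cv_shannon = c(0.2, 0.4))
  expect_error(multivariable_ols(prof, meta, "cv_shannon", "oral"),
               "P2", class = "microvar_error")
})

test_that("genus screens find the planted ecology and respect filters", {
  prod <- cohort_products(seed = 77L, n_patients = 16L)
  co <- prod$cohort
  gr <- relative_abundance(aggregate_genus(co$table))
  res <- suppressWarnings(
    genus_cv_correlation(gr, prod$profiles, co$meta, "cv_wu", "stool"))
  expect_s3_class(res, "association_result")
  expect_true(all(diff(res$statistic) <= 0))  # sorted by r descending
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  # cohort-wide rare genera are excluded by the 1% filter
  expect_true(all(rowMeans(gr[res$feature, colnames(gr) %in%
    co$meta$samples$sample_id[co$meta$samples$site == "stool"]]) >= 0.009))
  # patient_mean level runs and gives one observation per patient
  res_pm <- suppressWarnings(
    genus_cv_correlation(gr, prod$profiles, co$meta, "cv_wu", "stool",
                         level = "patient_mean"))
  expect_equal(unique(res_pm$n),
               sum(prod$profiles$site == "stool" &
                     !is.na(prod$profiles$cv_wu)))
})

test_that("genus_category_tests compares patient-level abundance across categories", {
  prod <- cohort_products(seed = 77L, n_patients = 16L)
  co <- prod$cohort
  gr <- relative_abundance(aggregate_genus(co$table))
  asg <- categorize(prod$profiles, "cv_wu")
  res <- genus_category_tests(gr, asg, co$meta, "stool")
  expect_true(all(c("median_stable", "median_variable", "stars") %in%
                    names(res)))
  expect_true(all(res$statistic >= 0))
  expect_equal(unique(res$n), sum(asg$site == "stool"))
})

test_that("outcome comparisons run per group and validate degenerate splits", {
  prod <- cohort_products(seed = 77L, n_patients = 16L)
  co <- prod$cohort
  res <- outcome_comparisons(prod$profiles, co$meta,
                             "infection_during_ic_any", "cv_shannon", "oral")
  expect_equal(res$n, res$n_with + res$n_without)
  expect_equal(res$statistic_name, "welch_t")
  # all patients forced into one group -> error
  meta2 <- co$meta
  meta2$patients$remission <- TRUE
  expect_error(outcome_comparisons(prod$profiles, meta2, "remission",
                                   "cv_shannon", "oral"),
               class = "mv_insufficient_data")
})

test_that("permuted labels yield calibrated type-I error in the genus screen", {
  prod <- cohort_products(seed = 78L, n_patients = 16L)
  co <- prod$cohort
  gr <- relative_abundance(aggregate_genus(co$table))
  prof <- prod$profiles
  set.seed(57)
  hits <- 0L; total <- 0L
  for (perm in 1:40) {
    p2 <- prof
    ix <- p2$site == "stool"
    p2$cv_wu[ix] <- sample(p2$cv_wu[ix])
    # patient_mean level: one observation per patient, so permuting patient
    # CVs is an exact exchangeable null and raw p should be uniform
    res <- suppressWarnings(
      genus_cv_correlation(gr, p2, co$meta, "cv_wu", "stool",
                           level = "patient_mean"))
    hits <- hits + sum(res$p_raw < 0.05)
    total <- total + nrow(res)
  }
  # tests share data across permutations, so the effective sample is
  # smaller than `total`; use the binomial band at n = genera x perms / 4
  ci <- qbinom(c(0.005, 0.995), ceiling(total / 4), 0.05) / ceiling(total / 4)
  expect_gte(hits / total, ci[1])
  expect_lte(hits / total, ci[2])
})
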