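test_that("coefficient_of_variation matches its definition", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(5), class = "mv_insufficient_data")
  expect_error(coefficient_of_variation(c(-2, 0, -1)),
               class = "mv_domain_error")
})

test_that("CV is scale invariant", {
  set.seed(41)
  for (rep in 1:50) {
    x <- rexp(sample(3:20, 1)) + 0.1
    k <- runif(1, 0.01, 100)
    expect_equal(coefficient_of_variation(k * x),
                 coefficient_of_variation(x), tolerance = 1e-10)
  }
})

test_that("alpha_cv delegates to the CV over a patient-site series", {
  meta <- tiny_meta()
  alpha <- data.frame(sample_id = paste0("s", 1:6),
                      shannon = c(1, 3, 2, 4, 4, 4),
                      simpson = rep(0.5, 6), chao1 = 1:6)
  expect_equal(alpha_cv(alpha, meta, "P1", "oral", "shannon"),
               coefficient_of_variation(c(1, 3, 2)))
  expect_equal(alpha_cv(alpha, meta, "P2", "oral", "shannon"), 0)
  # permutation invariance
  perm <- alpha[sample(6), ]
  expect_equal(alpha_cv(perm, meta, "P1", "oral", "shannon"),
               alpha_cv(alpha, meta, "P1", "oral", "shannon"))
  expect_error(alpha_cv(alpha, meta, "P1", "stool", "shannon"),
               class = "mv_insufficient_data")
})

test_that("beta_cv uses the selected within-patient pair set", {
  meta <- tiny_meta()
  ids <- paste0("s", 1:6)
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  m["s1", "s2"] <- m["s2", "s1"] <- 0.1
  m["s2", "s3"] <- m["s3", "s2"] <- 0.3
  m["s1", "s3"] <- m["s3", "s1"] <- 0.2
  m["s4", "s5"] <- m["s5", "s4"] <- 0.2
  m["s5", "s6"] <- m["s6", "s5"] <- 0.2
  m["s4", "s6"] <- m["s6", "s4"] <- 0.2
  dm <- distance_matrix(m)
  expect_equal(beta_cv(dm, meta, "P2", "oral"), 0)
  expect_equal(beta_cv(dm, meta, "P1", "oral", "all_pairs"), 0.5)
  # consecutive mode uses exactly the 2 order-adjacent distances {0.1, 0.3}
  expect_equal(beta_cv(dm, meta, "P1", "oral", "consecutive"),
               coefficient_of_variation(c(0.1, 0.3)))
})

test_that("build_profiles yields one row per eligible patient-site", {
  prod <- cohort_products()
  prof <- prod$profiles
  meta <- prod$cohort$meta
  eligible <- table(meta$samples$patient_id, meta$samples$site) >= 3
  expect_equal(nrow(prof), sum(eligible))
  expect_true(all(prof$n_samples >= 3))
  expect_true(all(prof[CV_MEASURES <- c("cv_shannon", "cv_simpson",
                                        "cv_chao1", "cv_uu", "cv_wu")] >= 0,
                  na.rm = TRUE))
})

test_that("profiles are invariant to sample-column permutation", {
  prod <- cohort_products()
  set.seed(43)
  tab <- prod$cohort$table
  perm <- sample(ncol(tab$counts))
  tab_p <- feature_table(tab$counts[, perm], tab$taxonomy)
  a_p <- suppressWarnings(alpha_table(tab_p))
  dms_p <- list(uu = suppressWarnings(beta_matrix(tab_p, prod$cohort$tree, "unweighted")),
                wu = suppressWarnings(beta_matrix(tab_p, prod$cohort$tree, "weighted_normalized")))
  prof_p <- build_profiles(a_p, dms_p, prod$cohort$meta)
  a <- as.data.frame(prod$profiles)
  b <- as.data.frame(prof_p)
  key <- order(a$patient_id, a$site)
  keyb <- order(b$patient_id, b$site)
  expect_equal(a[key, ], b[keyb, ], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("profiles below min_samples are skipped with a recorded reason", {
  meta <- tiny_meta()
  alpha <- data.frame(sample_id = paste0("s", 1:6),
                      shannon = 1:6, simpson = rep(0.5, 6), chao1 = 1:6)
  ids <- paste0("s", 1:6)
  m <- matrix(0.2, 6, 6, dimnames = list(ids, ids)); diag(m) <- 0
  dms <- list(uu = distance_matrix(m), wu = distance_matrix(m))
  prof <- build_profiles(alpha, dms, meta, min_samples = 4L)
  expect_equal(nrow(prof), 0L)
  expect_equal(nrow(attr(prof, "skipped")), 2L)
  expect_match(attr(prof, "skipped")$reason[1], "min_samples")
})

test_that("categorize implements the quartile rule with interpolation", {
  prof <- data.frame(patient_id = sprintf("P%d", 1:8), site = "oral",
                     cv_shannon = seq(0.1, 0.8, by = 0.1))
  asg <- categorize(prof, "cv_shannon")
  expect_setequal(asg$patient_id[asg$category == "stable"], c("P1", "P2"))
  expect_setequal(asg$patient_id[asg$category == "variable"], c("P7", "P8"))
  expect_equal(sum(asg$category == "average"), 4L)

  # ties everywhere -> everyone average
  prof$cv_shannon <- 0.5
  expect_true(all(categorize(prof, "cv_shannon")$category == "average"))

  expect_error(categorize(prof[1:3, ], "cv_shannon"),
               class = "mv_insufficient_data")
})

test_that("categories partition each site within the quartile sanity band", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(8:40, 1)
    prof <- data.frame(patient_id = sprintf("P%d", 1:n), site = "stool",
                       cv_wu = runif(n))
    asg <- categorize(prof, "cv_wu")
    expect_equal(nrow(asg), n)
    tab <- table(factor(asg$category,
                        levels = c("stable", "average", "variable")))
    expect_gte(tab[["stable"]], floor(n / 4) - 1)
    expect_lte(tab[["stable"]], ceiling(n / 4) + 1)
    expect_gte(tab[["variable"]], floor(n / 4) - 1)
    expect_lte(tab[["variable"]], ceiling(n / 4) + 1)
  }
})

test_that("cross_site_correlation handles exact and degenerate cases", {
  prof <- data.frame(
    patient_id = rep(sprintf("P%d", 1:5), 2),
    site = rep(c("oral", "stool"), each = 5),
    cv_shannon = c(1:5 / 10, 1:5 / 10))
  res <- cross_site_correlation(prof, "cv_shannon")
  expect_equal(res$r, 1)
  expect_equal(res$n, 5L)
  prof$cv_shannon[6:10] <- rev(prof$cv_shannon[6:10])
  expect_equal(cross_site_correlation(prof, "cv_shannon")$r, -1)
  expect_error(cross_site_correlation(prof[c(1, 6), ], "cv_shannon"),
               class = "mv_insufficient_data")
})

test_that("shared patient volatility induces a positive cross-site correlation", {
  # generator property at its stated settings: default cohort size with the
  # antibiotic coupling off, isolating the shared volatility factor
  # (reduced replicate count here; full scale belongs to the generator's
  # calibration record)
  sig_pos <- vapply(1:6, function(r) {
    co <- generate_cohort(cohort_config(n_patients = 59L, depth = 2000,
                                        abx_coupling = 0, seed = 900L + r))
    a <- suppressWarnings(alpha_table(co$table))
    dmw <- suppressWarnings(beta_matrix(co$table, co$tree,
                                        "weighted_normalized"))
    prof <- build_profiles(a, list(uu = dmw, wu = dmw), co$meta)
    x <- cross_site_correlation(prof, "cv_shannon")
    x$r > 0 && x$p < 0.05
  }, logical(1))
  expect_gte(sum(sig_pos), 5L)
})

test_that("group mean CVs increase with planted volatility level", {
  # 3 volatility levels, a few seeds each; monotone group means in both
  # cv_shannon and cv_wu (scaled-down version of the generator contract)
  sig <- c(0.1, 0.3, 0.8)
  means <- sapply(seq_along(sig), function(k) {
    cvs <- sapply(1:3, function(r) {
      co <- generate_cohort(cohort_config(
        n_patients = 10L, n_taxa = 50L, depth = 1500,
        sigma_low = sig[k], sigma_high = sig[k], frac_variable = 0,
        pathogen_coupling = 0, abx_coupling = 0, infection_coupling = 0,
        seed = 100L * k + r))
      a <- suppressWarnings(alpha_table(co$table))
      dmw <- suppressWarnings(beta_matrix(co$table, co$tree, "weighted_normalized"))
      prof <- build_profiles(a, list(uu = dmw, wu = dmw), co$meta)
      c(mean(prof$cv_shannon, na.rm = TRUE), mean(prof$cv_wu, na.rm = TRUE))
    })
    rowMeans(cvs)
  })
  expect_true(all(diff(means[1, ]) > 0))  # cv_shannon strictly increasing
  expect_true(all(diff(means[2, ]) > 0))  # cv_wu strictly increasing
})
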