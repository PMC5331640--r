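# Shared fixtures and independent oracles. The UniFrac oracle deliberately
# avoids the package's branch-incidence code path: branches and their leaf
# descendant sets are enumerated with phangorn::Descendants on the raw ape
# edge table, and the distance is accumulated branch by branch.

TOY_NEWICK <- "((A:1,B:1):1,(C:1,D:1):1):0;"

toy_tree <- function() parse_newick(TOY_NEWICK)

# brute-force branch partition: list of (length, tip labels) via phangorn
oracle_branches <- function(tree) {
  desc <- phangorn::Descendants(tree, type = "tips")
  lapply(seq_len(nrow(tree$edge)), function(k) {
    child <- tree$edge[k, 2L]
    list(length = tree$edge.length[k],
         leaves = tree$tip.label[desc[[child]]])
  })
}

oracle_unifrac <- function(tree, a, b, weighted = FALSE, normalized = TRUE) {
  branches <- oracle_branches(tree)
  pa_tot <- sum(a); pb_tot <- sum(b)
  num <- 0; den <- 0
  for (br in branches) {
    in_a <- sum(a[names(a) %in% br$leaves])
    in_b <- sum(b[names(b) %in% br$leaves])
    if (weighted) {
      num <- num + br$length * abs(in_a / pa_tot - in_b / pb_tot)
      den <- den + br$length * (in_a / pa_tot + in_b / pb_tot)
    } else {
      pres_a <- in_a > 0; pres_b <- in_b > 0
      if (xor(pres_a, pres_b)) num <- num + br$length
      if (pres_a || pres_b) den <- den + br$length
    }
  }
  if (weighted && !normalized) num else num / den
}

# random bifurcating tree with exp(1) branch lengths (ape's generator,
# independent of the package's tree construction)
random_test_tree <- function(n) {
  ape::rtree(n, br = stats::rexp)
}

random_community <- function(taxa, sparsity = 0.5) {
  counts <- rpois(length(taxa), 8) * rbinom(length(taxa), 1L, 1 - sparsity)
  if (sum(counts) == 0) counts[sample(length(taxa), 1L)] <- 1L
  setNames(as.integer(counts), taxa)
}

# tiny hand-built 2-patient metadata for unit tests
tiny_meta <- function() {
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    patient_id = rep(c("P1", "P2"), each = 3L),
    site = rep("oral", 6L),
    day = c(0, 3, 7, 0, 4, 8),
    order = rep(1:3, 2L),
    stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = c("P1", "P2"), age = c(50L, 60L),
    days_all_abx = c(10L, 20L), days_treatment_abx = c(5L, 9L),
    n_antibiotics = c(2L, 3L),
    pip_tazo_gt72h = c(TRUE, FALSE), cefepime_gt72h = c(FALSE, TRUE),
    carbapenem_gt72h = c(FALSE, FALSE),
    chemo_category = c("fludarabine", "hypomethylator"),
    infection_during_ic = c("MDI", "none"),
    infection_90d_post = c(TRUE, FALSE), remission = c(TRUE, TRUE),
    stringsAsFactors = FALSE)
  cohort_metadata(samples, patients)
}

small_cohort <- function(seed = 42L, n_patients = 12L) {
  generate_cohort(cohort_config(n_patients = n_patients, n_taxa = 60L,
                                depth = 2000, seed = seed))
}

# full pipeline products for a small cohort, memoised per test file run
cohort_products <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42L, n_patients = 12L) {
    key <- sprintf("s%d_n%d", seed, n_patients)
    if (!is.null(cache[[key]])) return(cache[[key]])
    co <- small_cohort(seed, n_patients)
    a <- suppressWarnings(alpha_table(co$table))
    dms <- list(uu = suppressWarnings(beta_matrix(co$table, co$tree, "unweighted")),
                wu = suppressWarnings(beta_matrix(co$table, co$tree, "weighted_normalized")))
    prof <- build_profiles(a, dms, co$meta)
    cache[[key]] <- list(cohort = co, alpha = a, dms = dms, profiles = prof)
    cache[[key]]
  }
})
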