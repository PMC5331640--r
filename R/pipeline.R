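# End-to-end orchestration: simulate (or load) -> diversity -> variability
# -> association screens, written as a reproducible artifact bundle with a
# machine-readable JSON summary. Runs are deterministic given the config:
# the summary is stamped with a config hash and the seed.

#' Build a validated pipeline run configuration
#'
#' Exactly one of `inputs` (paths to `table`, `tree`, `samples`,
#' `patients`) or `simulate` (arguments for [cohort_config()]) must be
#' given. Thresholds carry the pipeline defaults: all-pairs distance CVs,
#' min 3 samples per patient-site, 1% genus abundance filter,
#' 0.05/0.01/0.001 significance stars.
#'
#' @param out_dir output directory for the artifact bundle.
#' @param inputs named list of input paths, or `NULL`.
#' @param simulate named list of [cohort_config()] arguments, or `NULL`.
#' @param pair_mode,min_samples see [beta_cv()].
#' @param min_abundance genus inclusion threshold in (0, 1).
#' @param seed integer seed (also forwarded to the simulate block unless it
#'   sets its own).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, inputs = NULL, simulate = NULL,
                       pair_mode = "all_pairs", min_samples = 3L,
                       min_abundance = 0.01, seed = 1L) {
  if (is.null(inputs) == is.null(simulate))
    mv_validation_error("exactly one of 'inputs' and 'simulate' must be given")
  if (!is.null(inputs)) {
    miss <- setdiff(c("table", "tree", "samples", "patients"), names(inputs))
    if (length(miss))
      mv_validation_error(sprintf("inputs missing: %s",
                                  paste(miss, collapse = ", ")))
  }
  if (min_abundance <= 0 || min_abundance >= 1)
    mv_validation_error("min_abundance must lie in (0, 1)")
  structure(list(out_dir = out_dir, inputs = inputs, simulate = simulate,
                 pair_mode = match.arg(pair_mode, c("all_pairs", "consecutive")),
                 min_samples = as.integer(min_samples),
                 min_abundance = min_abundance, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) mv_format_error(sprintf("file not found: '%s'", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

# 32-bit polynomial rolling hash over the serialized config; cheap content
# stamp for reproducibility checks (no external hashing dependency
# available). Carried in double precision: all intermediates stay below
# 2^53, so the arithmetic is exact.
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2L))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

write_tsv_num <- function(df, path) {
  # fixed significant-digit formatting so reruns are byte-identical
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full variability pipeline
#'
#' Loads or simulates the cohort, computes the per-sample alpha table and
#' both UniFrac matrices, builds variability profiles and stability
#' categories (by `cv_shannon` and `cv_wu`), and runs the association
#' screens per site: genus-vs-CV correlations, genus-vs-category
#' Kruskal-Wallis, outcome comparisons, and the covariate regression grid.
#' Writes nine artifacts into `config$out_dir` (`alpha.tsv`,
#' `beta_unweighted.tsv`, `beta_weighted.tsv`, `profiles.tsv`,
#' `categories.tsv`, `assoc_genus_cv.tsv`, `assoc_genus_category.tsv`,
#' `assoc_outcomes.tsv`, `summary.json`) plus `regression_pvalues.tsv`.
#' Rerunning with the same config reproduces identical bytes.
#'
#' @param config a [run_config()] or path to a JSON config.
#' @return Invisibly, a list with the in-memory results and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- stage("simulate", generate_cohort(do.call(cohort_config, sim_args)))
    table <- cohort$table; tree <- cohort$tree; meta <- cohort$meta
  } else {
    table <- stage("load", read_feature_table(config$inputs$table))
    tree <- stage("load", read_newick(config$inputs$tree))
    meta <- stage("load", read_metadata(config$inputs$samples,
                                        config$inputs$patients))
  }

  alpha <- stage("diversity", alpha_table(table))
  dm_uu <- stage("diversity", beta_matrix(table, tree, "unweighted"))
  dm_wu <- stage("diversity", beta_matrix(table, tree, "weighted_normalized"))

  profiles <- stage("variability",
                    build_profiles(alpha, list(uu = dm_uu, wu = dm_wu), meta,
                                   pair_mode = config$pair_mode,
                                   min_samples = config$min_samples))
  categories <- stage("variability", rbind(categorize(profiles, "cv_shannon"),
                                           categorize(profiles, "cv_wu")))
  xsite <- stage("variability", lapply(
    setNames(nm = c("cv_shannon", "cv_wu")),
    function(m) tryCatch(cross_site_correlation(profiles, m),
                         microvar_error = function(e) NULL)))

  genus_rel <- stage("association",
                     relative_abundance(drop_empty_samples(aggregate_genus(table))))
  assoc_cv <- list(); assoc_cat <- list(); assoc_out <- list()
  for (site in SITE_LEVELS) {
    for (m in c("cv_shannon", "cv_wu")) {
      r <- stage("association", genus_cv_correlation(
        genus_rel, profiles, meta, m, site,
        min_abundance = config$min_abundance))
      if (nrow(r)) { r$site <- site; r$measure <- m }
      assoc_cv[[paste(site, m)]] <- r
      rc <- stage("association", tryCatch(
        genus_category_tests(genus_rel,
                             categories[categories$measure == m, ], meta,
                             site, min_abundance = config$min_abundance),
        microvar_error = function(e) NULL))
      if (!is.null(rc) && nrow(rc)) { rc$site <- site; rc$measure <- m }
      assoc_cat[[paste(site, m)]] <- rc
    }
    for (outc in c("infection_during_ic_any", "infection_90d_post", "remission")) {
      ro <- stage("association", tryCatch(
        outcome_comparisons(profiles, meta, outc, "cv_shannon", site),
        microvar_error = function(e) NULL))
      assoc_out[[paste(site, outc)]] <- ro
    }
  }
  regression <- stage("association", tryCatch(
    multivariable_grid(profiles, meta), microvar_error = function(e) NULL))

  paths <- c(alpha = "alpha.tsv", beta_uu = "beta_unweighted.tsv",
             beta_wu = "beta_weighted.tsv", profiles = "profiles.tsv",
             categories = "categories.tsv", assoc_cv = "assoc_genus_cv.tsv",
             assoc_cat = "assoc_genus_category.tsv",
             assoc_out = "assoc_outcomes.tsv", summary = "summary.json")
  paths <- setNames(file.path(config$out_dir, paths), names(paths))

  write_tsv_num(alpha, paths[["alpha"]])
  write_distance_matrix(dm_uu, paths[["beta_uu"]])
  write_distance_matrix(dm_wu, paths[["beta_wu"]])
  write_tsv_num(as.data.frame(profiles), paths[["profiles"]])
  write_tsv_num(categories, paths[["categories"]])
  bind_assoc <- function(lst) {
    lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
    if (!length(lst)) return(data.frame())
    do.call(rbind, c(lapply(lst, as.data.frame), make.row.names = FALSE))
  }
  write_tsv_num(bind_assoc(assoc_cv), paths[["assoc_cv"]])
  write_tsv_num(bind_assoc(assoc_cat), paths[["assoc_cat"]])
  write_tsv_num(bind_assoc(assoc_out), paths[["assoc_out"]])
  if (!is.null(regression)) {
    reg_df <- data.frame(covariate = rownames(regression),
                         as.data.frame(regression), check.names = FALSE)
    write_tsv_num(reg_df, file.path(config$out_dir, "regression_pvalues.tsv"))
  }

  site_summary <- lapply(setNames(nm = SITE_LEVELS), function(s) {
    p <- profiles[profiles$site == s, , drop = FALSE]
    lapply(setNames(nm = CV_MEASURES), function(m)
      list(mean = if (nrow(p)) mean(p[[m]], na.rm = TRUE) else NA,
           sd = if (nrow(p)) sd(p[[m]], na.rm = TRUE) else NA,
           n = sum(!is.na(p[[m]]))))
  })
  skipped <- attr(profiles, "skipped")
  # hash the scientific configuration only: where the artifacts land must
  # not change the stamp
  hash_cfg <- unclass(config)[setdiff(names(config), "out_dir")]
  summary <- list(
    config_hash = config_hash(hash_cfg), seed = config$seed,
    n_samples = ncol(table$counts), n_taxa = nrow(table$counts),
    n_patients = nrow(meta$patients),
    n_profiles = nrow(profiles),
    n_skipped_patient_sites = if (is.null(skipped)) 0L else nrow(skipped),
    per_site_cv = site_summary,
    cross_site = xsite,
    screen_hits = list(
      genus_cv = sum(vapply(assoc_cv, function(x)
        if (is.null(x) || !nrow(x)) 0L else sum(x$p_adj < 0.05), integer(1L))),
      genus_category = sum(vapply(assoc_cat, function(x)
        if (is.null(x) || !nrow(x)) 0L else sum(x$p_adj < 0.05), integer(1L))),
      outcomes = sum(vapply(assoc_out, function(x)
        if (is.null(x) || !nrow(x)) 0L else sum(x$p_raw < 0.05), integer(1L)))))
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")

  invisible(list(table = table, tree = tree, meta = meta, alpha = alpha,
                 dm_uu = dm_uu, dm_wu = dm_wu, profiles = profiles,
                 categories = categories, cross_site = xsite,
                 assoc_cv = assoc_cv, assoc_cat = assoc_cat,
                 assoc_out = assoc_out, regression = regression,
                 summary = summary, paths = paths))
}
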