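# Seeded generator of longitudinal two-site cohorts with known ground
# truth. The stated world it emulates: ~59 hospitalized adults sampled at
# two body sites (oral, stool) over roughly four weeks of induction
# chemotherapy, 6-9 samples per patient per site, mean sequencing depth
# 28,622 reads/sample, with (a) a patient-level volatility factor shared by
# both sites (driving the observed oral<->stool CV correlation), (b)
# pathogen-genus blooms and persistent pathogen/commensal abundance shifts
# tied to volatility, (c) an oral-specific antibiotic-exposure factor, and
# (d) infection outcomes drawn from logits in the planted volatility.

# Genus roster: habitat preference and ecological role drive the
# site-structured Dirichlet baseline and the planted abundance shifts.
GENUS_ROSTER <- data.frame(
  genus = c("Streptococcus", "Staphylococcus", "Stenotrophomonas", "Rothia",
            "Veillonella", "Actinomyces", "Neisseria", "Haemophilus",
            "Prevotella", "Fusobacterium", "Granulicatella", "Gemella",
            "Enterococcus", "Akkermansia", "Pseudobutyrivibrio",
            "Subdoligranulum", "Lactobacillus", "Bacteroides", "Blautia",
            "Faecalibacterium", "Roseburia", "Bifidobacterium",
            "Escherichia", "Clostridium", "unclassified"),
  habitat = c("oral", "both", "both", "oral", "oral", "oral", "oral", "oral",
              "both", "oral", "oral", "oral",
              "both", "stool", "stool", "stool", "both", "stool", "stool",
              "stool", "stool", "stool", "stool", "stool", "both"),
  role = c("pathogen", "pathogen", "pathogen", "neutral", "neutral",
           "neutral", "neutral", "neutral", "neutral", "neutral", "neutral",
           "neutral", "pathogen", "commensal", "commensal", "commensal",
           "neutral", "neutral", "neutral", "commensal", "neutral",
           "neutral", "neutral", "neutral", "neutral"),
  stringsAsFactors = FALSE)

#' Synthetic cohort configuration
#'
#' Defaults encode the emulated study design: 59 patients, two sites, 6-9
#' samples per patient per site over ~28 days, 120 taxa in 25 genera, mean
#' sequencing depth 28,622 reads. `sigma_low`/`sigma_high` are the
#' log-composition random-walk step scales of planted stable vs. volatile
#' patients; `pathogen_coupling` scales both the persistent pathogen (+) /
#' commensal (-) abundance shifts with volatility and the bloom spikes;
#' `abx_coupling` couples an oral-specific antibiotic-exposure factor to
#' oral volatility; `infection_coupling` is the logit slope of both
#' infection outcomes in the planted volatility z-score. Setting all three
#' couplings to 0 with `sigma_high = sigma_low` gives a fully null cohort.
#'
#' @param n_patients number of patients (>= 8; default 59).
#' @param samples_range integer range (lo, hi) for the per-patient,
#'   per-site sample count draw (default 6-9).
#' @param n_taxa number of taxa spread over the 25-genus roster
#'   (default 120).
#' @param sigma_low,sigma_high random-walk step scale of stable / volatile
#'   patients (0 < sigma_low < sigma_high; defaults 0.15 / 0.6).
#' @param frac_variable fraction of patients planted volatile (default 0.5).
#' @param pathogen_coupling,abx_coupling,infection_coupling planted effect
#'   strengths, all >= 0 (defaults 3 / 1.8 / 1.5).
#' @param depth mean reads per sample, Poisson (default 28622).
#' @param seed integer seed; all randomness derives from it.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 59L, samples_range = c(6L, 9L),
                          n_taxa = 120L, sigma_low = 0.15, sigma_high = 0.6,
                          frac_variable = 0.5, pathogen_coupling = 3,
                          abx_coupling = 1.8, infection_coupling = 1.5,
                          depth = 28622, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              samples_range = as.integer(samples_range),
              n_taxa = as.integer(n_taxa), sigma_low = sigma_low,
              sigma_high = sigma_high, frac_variable = frac_variable,
              pathogen_coupling = pathogen_coupling,
              abx_coupling = abx_coupling,
              infection_coupling = infection_coupling,
              depth = depth, seed = as.integer(seed))
  if (cfg$n_patients < 8L)
    mv_validation_error("n_patients must be >= 8")
  if (length(cfg$samples_range) != 2L || any(cfg$samples_range < 2L) ||
      cfg$samples_range[1] > cfg$samples_range[2])
    mv_validation_error("samples_range must be an increasing pair >= 2")
  if (cfg$n_taxa < nrow(GENUS_ROSTER))
    mv_validation_error(sprintf("n_taxa must be >= %d (one per genus)",
                                nrow(GENUS_ROSTER)))
  if (!(cfg$sigma_high >= cfg$sigma_low && cfg$sigma_low > 0))
    mv_validation_error("need sigma_high >= sigma_low > 0")
  if (cfg$depth <= 0) mv_validation_error("depth must be positive")
  if (cfg$frac_variable < 0 || cfg$frac_variable > 1)
    mv_validation_error("frac_variable must lie in [0, 1]")
  if (cfg$pathogen_coupling < 0 || cfg$abx_coupling < 0 ||
      cfg$infection_coupling < 0)
    mv_validation_error("couplings must be >= 0")
  structure(cfg, class = "cohort_config")
}

# Recursive random bifurcating Newick over `units` (already-formatted
# subtree strings), exponential branch lengths with the given rate.
rand_split_newick <- function(units, rate) {
  n <- length(units)
  if (n == 1L) return(sprintf("%s:%.8f", units, rexp(1, rate)))
  units <- sample(units)
  k <- if (n == 2L) 1L else sample(n - 1L, 1L)
  left <- rand_split_newick(units[seq_len(k)], rate)
  right <- rand_split_newick(units[(k + 1L):n], rate)
  sprintf("(%s,%s):%.8f", left, right, rexp(1, rate))
}

build_tree <- function(taxa, genus_of) {
  genera <- unique(genus_of)
  clades <- vapply(genera, function(g) {
    members <- taxa[genus_of == g]
    if (length(members) == 1L) sprintf("%s", members)
    else {
      # short within-genus branches keep genus-mates phylogenetically close
      sub <- rand_split_newick(members, rate = 5)
      sub <- sub("[:][0-9.]+$", "", sub)  # stem length comes from backbone
      sub
    }
  }, character(1L))
  backbone <- rand_split_newick(clades, rate = 1)
  backbone <- sub("[:][0-9.]+$", "", backbone)
  tree <- parse_newick(paste0(backbone, ";"))
  validate_tree(tree)
}

#' Random genus-structured phylogeny
#'
#' Random bifurcating rooted tree with exponential(1) backbone branch
#' lengths; all taxa of one genus sit inside one clade with shorter
#' (exponential, mean 0.2) internal branches, so genus-mates are closer to
#' each other than to other genera on average.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @return A `phylo` with leaf labels `<Genus>_t<k>`.
#' @export
generate_tree <- function(n_taxa, seed) {
  if (n_taxa < 2L) mv_validation_error("n_taxa must be >= 2")
  with_local_seed(seed, {
    genus_sizes <- allocate_taxa(n_taxa)
    taxa <- unlist(lapply(seq_len(nrow(GENUS_ROSTER)), function(i)
      sprintf("%s_t%d", GENUS_ROSTER$genus[i], seq_len(genus_sizes[i]))))
    genus_of <- sub("_t[0-9]+$", "", taxa)
    build_tree(taxa, genus_of)
  })
}

# Allocate n_taxa across the roster, at least one per genus; extras
# multinomial-uniform. For n_taxa below the roster size, the first n genera
# get one taxon each.
allocate_taxa <- function(n_taxa) {
  ng <- nrow(GENUS_ROSTER)
  if (n_taxa < ng) return(c(rep(1L, n_taxa), rep(0L, ng - n_taxa)))
  extra <- drop(rmultinom(1L, n_taxa - ng, rep(1, ng)))
  rep(1L, ng) + extra
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate a synthetic longitudinal two-site cohort
#'
#' Per patient and site: a genus-structured Dirichlet baseline composition
#' (site-specific genus priors, with pathogen/commensal prior shifted by
#' the patient's planted volatility when `pathogen_coupling > 0`); a
#' Gaussian random walk on log-composition with per-site step scale
#' `sigma_p * exp(site noise)` (oral additionally multiplied by
#' `exp(abx_coupling * z_abx)`); bloom spikes of one pathogen genus in
#' volatile patients; multinomial counts at Poisson(depth). Antibiotic-day
#' covariates derive from `z_abx`; infection outcomes are Bernoulli with
#' logit linear in the planted volatility z-score. All randomness flows
#' from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return List of class `synthetic_cohort` with elements `table`
#'   ([feature_table()]), `tree` (`phylo`), `meta` ([cohort_metadata()]),
#'   `truth` (data.frame of planted per-patient parameters) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  np <- config$n_patients
  genus_sizes <- allocate_taxa(config$n_taxa)
  roster <- GENUS_ROSTER[genus_sizes > 0L, , drop = FALSE]
  genus_sizes <- genus_sizes[genus_sizes > 0L]
  taxa <- unlist(lapply(seq_len(nrow(roster)), function(i)
    sprintf("%s_t%d", roster$genus[i], seq_len(genus_sizes[i]))))
  genus_of <- sub("_t[0-9]+$", "", taxa)
  tree <- build_tree(taxa, genus_of)

  patient_ids <- sprintf("P%03d", seq_len(np))
  volatile <- rbinom(np, 1L, config$frac_variable) == 1L
  # two planted levels plus a continuous patient-level spread shared by
  # both sites; z_vol is the group z-score (exactly zero when a single
  # level is used, keeping the null configuration exactly null)
  z_pat <- rnorm(np)
  sigma_p <- ifelse(volatile, config$sigma_high, config$sigma_low) *
    exp(0.35 * z_pat)
  lg <- log(ifelse(volatile, config$sigma_high, config$sigma_low))
  z_vol <- if (sd(lg) > 0) (lg - mean(lg)) / sd(lg) else rep(0, np)
  # abundance shifts track the full realized volatility (group + shared
  # spread) so genus-vs-CV correlations reflect the planted ecology
  z_role <- z_vol + 0.35 * z_pat
  z_abx <- rnorm(np)

  site_sigma <- list(
    oral = sigma_p * exp(config$abx_coupling * z_abx + rnorm(np, 0, 0.15)),
    stool = sigma_p * exp(rnorm(np, 0, 0.15)))

  # days on treatment antibiotics and the prophylaxis component are driven
  # by separate factors so the two day-count covariates are not collinear;
  # only the total (prophylaxis-inclusive) tracks the oral exposure factor
  days_treatment <- pmax(0L, round(7 + 3 * rnorm(np)))
  days_prophylaxis <- pmax(0L, round(7 + 5 * z_abx + rnorm(np, 0, 1)))
  patients <- data.frame(
    patient_id = patient_ids,
    age = pmin(85L, pmax(19L, round(rnorm(np, 52, 14)))),
    days_all_abx = days_treatment + days_prophylaxis,
    stringsAsFactors = FALSE)
  patients$days_treatment_abx <- days_treatment
  patients$n_antibiotics <- 1L + rpois(np, 2)
  patients$pip_tazo_gt72h <- rbinom(np, 1L, 0.45) == 1L
  patients$cefepime_gt72h <- rbinom(np, 1L, 0.35) == 1L
  patients$carbapenem_gt72h <- rbinom(np, 1L, 0.2) == 1L
  patients$chemo_category <- sample(CHEMO_LEVELS, np, replace = TRUE,
                                    prob = c(0.4, 0.3, 0.2, 0.1))
  infected_ic <- rbinom(np, 1L, plogis(qlogis(0.45) +
                                         config$infection_coupling * z_vol)) == 1L
  patients$infection_during_ic <- ifelse(
    infected_ic, sample(c("MDI", "clinical"), np, replace = TRUE), "none")
  patients$infection_90d_post <- rbinom(np, 1L, plogis(qlogis(0.30) +
                                                         config$infection_coupling * z_vol)) == 1L
  patients$remission <- rbinom(np, 1L, 0.75) == 1L

  # site-specific genus priors for the Dirichlet baseline
  habitat_logw <- function(site)
    ifelse(roster$habitat == site | roster$habitat == "both", 0, -2)
  role_shift <- function(zv)
    0.5 * config$pathogen_coupling * zv *
    (roster$role == "pathogen") -
    0.5 * config$pathogen_coupling * zv * (roster$role == "commensal")
  pathogen_taxa <- which(genus_of %in% roster$genus[roster$role == "pathogen"])

  sample_rows <- list()
  count_cols <- list()
  bloom_flag <- matrix(FALSE, np, 2, dimnames = list(patient_ids, SITE_LEVELS))
  for (i in seq_len(np)) {
    for (site in SITE_LEVELS) {
      lo <- config$samples_range[1]; hi <- config$samples_range[2]
      ts <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
      days <- cumsum(c(sample(0:2, 1L), sample(2:5, ts - 1L, replace = TRUE)))
      genus_alpha <- exp(habitat_logw(site) + role_shift(z_role[i]))
      genus_alpha <- genus_alpha / sum(genus_alpha) * 16
      genus_p <- rdirichlet1(genus_alpha)
      taxon_p <- unlist(lapply(seq_len(nrow(roster)), function(g) {
        w <- rdirichlet1(rep(1, genus_sizes[g]))
        genus_p[g] * w
      }))
      eta0 <- log(pmax(taxon_p, 1e-8))
      sig <- site_sigma[[site]][i]
      steps <- matrix(rnorm(ts * length(taxa), 0, sig), ts, length(taxa))
      steps[1L, ] <- 0
      eta <- sweep(apply(steps, 2L, cumsum), 2L, eta0, "+")
      if (ts == 1L) eta <- matrix(eta0, 1L)
      if (volatile[i] && config$pathogen_coupling > 0) {
        bloom_flag[i, site] <- TRUE
        g <- sample(roster$genus[roster$role == "pathogen"], 1L)
        win_len <- max(2L, round(ts / 3))
        start <- sample(seq_len(max(1L, ts - win_len + 1L)), 1L)
        rows <- start:min(ts, start + win_len - 1L)
        eta[rows, genus_of == g] <- eta[rows, genus_of == g] +
          0.8 * config$pathogen_coupling
      }
      p_t <- exp(eta - apply(eta, 1L, max))
      p_t <- p_t / rowSums(p_t)
      depths <- pmax(1L, rpois(ts, config$depth))
      cnt <- vapply(seq_len(ts), function(t)
        drop(rmultinom(1L, depths[t], p_t[t, ])), integer(length(taxa)))
      ids <- sprintf("%s_%s_%d", patient_ids[i], site, seq_len(ts))
      colnames(cnt) <- ids
      count_cols[[length(count_cols) + 1L]] <- cnt
      sample_rows[[length(sample_rows) + 1L]] <- data.frame(
        sample_id = ids, patient_id = patient_ids[i], site = site,
        day = days, order = seq_len(ts), stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, count_cols)
  rownames(counts) <- taxa
  table <- feature_table(counts, setNames(genus_of, taxa))
  meta <- cohort_metadata(do.call(rbind, sample_rows), patients)
  truth <- data.frame(
    patient_id = patient_ids, volatile = volatile, sigma_p = sigma_p,
    z_vol = z_vol, z_abx = z_abx,
    sigma_oral = site_sigma$oral, sigma_stool = site_sigma$stool,
    bloom_oral = bloom_flag[, "oral"], bloom_stool = bloom_flag[, "stool"],
    stringsAsFactors = FALSE)
  structure(list(table = table, tree = tree, meta = meta, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients, %d samples, %d taxa (seed %d)\n",
              nrow(x$meta$patients), ncol(x$table$counts),
              nrow(x$table$counts), x$config$seed))
  invisible(x)
}

#' Write a pinned small cohort fixture to disk
#'
#' Generates a 12-patient cohort at a fixed seed and writes it in every
#' external interface format (`table.tsv`, `tree.nwk`, `samples.tsv`,
#' `patients.tsv`, `truth.tsv`). Byte-identical across runs.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed fixture seed (default 20240317).
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixture <- function(out_dir, seed = 20240317) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort_config(n_patients = 12L, n_taxa = 60L, depth = 2000,
                       seed = seed)
  cohort <- generate_cohort(cfg)
  paths <- c(table = file.path(out_dir, "table.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             samples = file.path(out_dir, "samples.tsv"),
             patients = file.path(out_dir, "patients.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_feature_table(cohort$table, paths[["table"]])
  write_newick(cohort$tree, paths[["tree"]])
  write_metadata(cohort$meta, paths[["samples"]], paths[["patients"]])
  write.table(cohort$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
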