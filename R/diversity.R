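# Alpha-diversity indices and UniFrac beta-diversity distances.
#
# Conventions (the upstream study names the indices but none of the
# variants, so these follow the phyloseq/vegan family and are fixed here):
# Shannon uses the natural log; Simpson is the Gini-Simpson form 1 - sum p^2;
# Chao-1 is the bias-corrected estimator. No rarefaction by default —
# metrics are computed on relative abundances of the full counts; an
# optional seeded without-replacement rarefaction is provided for
# sensitivity analysis. Weighted UniFrac defaults to the normalized form so
# values lie in [0, 1] and CVs are comparable across patients.

check_community <- function(v) {
  if (length(v) == 0L || anyNA(v) || any(v < 0))
    mv_validation_error("community vector must be non-negative and non-missing")
  if (sum(v) <= 0)
    mv_domain_error("community vector has zero total count")
  invisible(v)
}

#' Alpha-diversity indices of a single community
#'
#' `shannon()` returns \eqn{-\sum p_i \ln p_i}; `simpson()` the
#' Gini-Simpson index \eqn{1 - \sum p_i^2}; `chao1()` the bias-corrected
#' Chao-1 richness estimate
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} where \eqn{F_1, F_2} are
#' the singleton and doubleton counts (integer counts required).
#'
#' @param v numeric vector of taxon counts for one sample (names optional).
#' @return A single non-negative number.
#' @export
shannon <- function(v) {
  check_community(v)
  p <- v[v > 0] / sum(v)
  -sum(p * log(p))
}

#' @rdname shannon
#' @export
simpson <- function(v) {
  check_community(v)
  p <- v[v > 0] / sum(v)
  1 - sum(p^2)
}

#' @rdname shannon
#' @export
chao1 <- function(v) {
  check_community(v)
  if (any(v != floor(v)))
    mv_validation_error("chao1 requires integer counts")
  s_obs <- sum(v > 0)
  f1 <- sum(v == 1)
  f2 <- sum(v == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

align_community <- function(v, tips) {
  nm <- names(v)
  if (is.null(nm))
    mv_validation_error("community vectors must be named by taxon id")
  pos <- nm[v > 0]
  unknown <- setdiff(pos, tips)
  if (length(unknown))
    mv_validation_error(sprintf("taxon '%s' is not a leaf of the tree",
                                unknown[1L]))
  out <- setNames(numeric(length(tips)), tips)
  out[nm[nm %in% tips]] <- v[nm %in% tips]
  out
}

#' UniFrac distances between two communities
#'
#' Unweighted UniFrac is the fraction of observed branch length unique to
#' one community: \eqn{\sum_b l_b [A_b \neq B_b] / \sum_b l_b [A_b \vee
#' B_b]} with presence defined as count > 0. Weighted UniFrac is
#' \eqn{\sum_b l_b |p_a(b) - p_b(b)|} where \eqn{p_x(b)} is the fraction
#' of community x's total counts descending through branch b; the
#' normalized form divides by \eqn{\sum_b l_b (p_a(b) + p_b(b))} and lies
#' in [0, 1].
#'
#' @param tree a rooted `phylo` with branch lengths whose leaves include
#'   every taxon with positive count.
#' @param a,b named non-negative count vectors (taxon id -> count), each
#'   with positive total.
#' @param normalized for `weighted_unifrac`, divide by the total
#'   abundance-weighted branch length (default `TRUE`).
#' @return A distance; unweighted and normalized-weighted values lie in
#'   [0, 1].
#' @export
unweighted_unifrac <- function(tree, a, b) {
  tree <- validate_tree(tree)
  if (inherits(tree, "single_leaf") || length(tree$tip.label) < 2L)
    mv_validation_error("UniFrac requires a tree with at least 2 leaves")
  check_community(a); check_community(b)
  bi <- branch_incidence(tree)
  tips <- colnames(bi$incidence)
  pa <- (align_community(a, tips) > 0) + 0
  pb <- (align_community(b, tips) > 0) + 0
  in_a <- drop(bi$incidence %*% pa) > 0
  in_b <- drop(bi$incidence %*% pb) > 0
  shared <- sum(bi$lengths[in_a | in_b])
  if (shared == 0) mv_domain_error("no observed branch length")
  sum(bi$lengths[xor(in_a, in_b)]) / shared
}

#' @rdname unweighted_unifrac
#' @export
weighted_unifrac <- function(tree, a, b, normalized = TRUE) {
  tree <- validate_tree(tree)
  if (inherits(tree, "single_leaf") || length(tree$tip.label) < 2L)
    mv_validation_error("UniFrac requires a tree with at least 2 leaves")
  check_community(a); check_community(b)
  bi <- branch_incidence(tree)
  tips <- colnames(bi$incidence)
  pa <- align_community(a, tips); pa <- pa / sum(pa)
  pb <- align_community(b, tips); pb <- pb / sum(pb)
  wa <- drop(bi$incidence %*% pa)
  wb <- drop(bi$incidence %*% pb)
  raw <- sum(bi$lengths * abs(wa - wb))
  if (!normalized) return(raw)
  denom <- sum(bi$lengths * (wa + wb))
  if (denom == 0) mv_domain_error("no observed branch length")
  raw / denom
}

drop_empty_samples <- function(table) {
  totals <- colSums(table$counts)
  empty <- colnames(table$counts)[totals == 0]
  if (length(empty)) {
    warning(sprintf("dropping %d zero-count sample(s): %s", length(empty),
                    paste(empty, collapse = ", ")), call. = FALSE)
    if (length(empty) == ncol(table$counts))
      mv_domain_error("all samples have zero total count")
    table <- feature_table(table$counts[, totals > 0, drop = FALSE],
                           table$taxonomy)
  }
  table
}

#' Per-sample alpha-diversity table
#'
#' One row per sample with `shannon`, `simpson` and `chao1`. Samples with
#' zero total count are dropped with a warning.
#'
#' @param table a [feature_table()].
#' @return data.frame with columns `sample_id`, `shannon`, `simpson`,
#'   `chao1`.
#' @export
alpha_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  table <- drop_empty_samples(table)
  counts <- table$counts
  data.frame(
    sample_id = colnames(counts),
    shannon = apply(counts, 2L, shannon),
    simpson = apply(counts, 2L, simpson),
    chao1 = apply(counts, 2L, chao1),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise UniFrac distance matrix for all samples of a feature table
#'
#' Computes the full symmetric matrix via a branch-incidence decomposition
#' of the tree (each branch's abundance flow per sample), which is
#' algebraically identical to calling the pairwise functions but vectorised
#' over samples. Samples with zero total count are dropped with a warning.
#'
#' @param table a [feature_table()] whose taxa are all leaves of `tree`.
#' @param tree a rooted `phylo` with branch lengths.
#' @param metric `"unweighted"`, `"weighted_normalized"` or
#'   `"weighted_raw"`.
#' @return A [distance_matrix()] over the retained samples.
#' @export
beta_matrix <- function(table, tree,
                        metric = c("unweighted", "weighted_normalized",
                                   "weighted_raw")) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "feature_table"))
  tree <- validate_tree(tree)
  table <- drop_empty_samples(table)
  counts <- table$counts
  unknown <- setdiff(rownames(counts), tree$tip.label)
  if (length(unknown))
    mv_validation_error(sprintf("taxon '%s' is not a leaf of the tree",
                                unknown[1L]))
  bi <- branch_incidence(tree)
  # taxa x samples relative abundances aligned to tree tips
  tips <- colnames(bi$incidence)
  P <- matrix(0, length(tips), ncol(counts), dimnames = list(tips, colnames(counts)))
  P[rownames(counts), ] <- sweep(counts, 2L, colSums(counts), "/")
  L <- bi$lengths
  n <- ncol(P)
  ids <- colnames(counts)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (metric == "unweighted") {
    Pe <- (bi$incidence %*% (P > 0)) > 0   # branches x samples presence
    storage.mode(Pe) <- "double"
    for (i in seq_len(n)) {
      o <- Pe[, i]
      uniq <- colSums(L * abs(Pe - o))
      shared <- colSums(L * ((Pe + o) > 0))
      di <- ifelse(shared > 0, uniq / shared, 0)
      d[i, ] <- di
    }
  } else {
    W <- bi$incidence %*% P                 # branches x samples flow
    for (i in seq_len(n)) {
      o <- W[, i]
      raw <- colSums(L * abs(W - o))
      if (metric == "weighted_raw") {
        d[i, ] <- raw
      } else {
        denom <- colSums(L * (W + o))
        d[i, ] <- ifelse(denom > 0, raw / denom, 0)
      }
    }
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  distance_matrix(d)
}

#' Rarefy a feature table (optional sensitivity preprocessing)
#'
#' Without-replacement subsampling of each sample column to a common depth,
#' with a recorded seed. Samples shallower than `depth` are dropped with a
#' warning. Not applied by default anywhere in the pipeline.
#'
#' @param table a [feature_table()].
#' @param depth target counts per sample.
#' @param seed integer seed.
#' @return A rarefied [feature_table()].
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "feature_table"), depth > 0)
  counts <- table$counts
  totals <- colSums(counts)
  shallow <- colnames(counts)[totals < depth]
  if (length(shallow)) {
    warning(sprintf("dropping %d sample(s) shallower than %d: %s",
                    length(shallow), depth,
                    paste(shallow, collapse = ", ")), call. = FALSE)
    counts <- counts[, totals >= depth, drop = FALSE]
  }
  if (ncol(counts) == 0L) mv_domain_error("no samples at requested depth")
  out <- with_local_seed(seed, {
    apply(counts, 2L, function(col) {
      pool <- rep.int(seq_along(col), col)
      keep <- sample(pool, depth)
      tabulate(keep, nbins = length(col))
    })
  })
  rownames(out) <- rownames(counts)
  feature_table(out, table$taxonomy)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
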