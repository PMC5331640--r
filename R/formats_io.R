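# Readers/writers for the package's external representations: QIIME-classic
# style feature tables, the two metadata TSVs, and square labelled distance
# matrices. All readers validate cross-references before returning.

CHEMO_LEVELS <- c("fludarabine", "non_fludarabine_high_intensity",
                  "hypomethylator", "other")
INFECTION_LEVELS <- c("MDI", "clinical", "none")
SITE_LEVELS <- c("oral", "stool")

PATIENT_COLUMNS <- c("patient_id", "age", "days_all_abx", "days_treatment_abx",
                     "n_antibiotics", "pip_tazo_gt72h", "cefepime_gt72h",
                     "carbapenem_gt72h", "chemo_category", "infection_during_ic",
                     "infection_90d_post", "remission")
SAMPLE_COLUMNS <- c("sample_id", "patient_id", "site", "day", "order")

#' Construct a validated feature table
#'
#' A feature table is the taxon-by-sample count matrix all diversity and
#' association machinery consumes: non-negative integer counts, unique taxon
#' and sample identifiers, and a genus label for every taxon
#' (`"unclassified"` for taxa without one).
#'
#' @param counts integer matrix, taxa in rows, samples in columns, with
#'   dimnames giving taxon and sample ids.
#' @param taxonomy named character vector mapping every taxon id to a genus
#'   label; `NULL` maps all taxa to `"unclassified"`.
#' @return An object of class `feature_table`: a list with elements
#'   `counts` (integer matrix) and `taxonomy` (named character vector).
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L)
    mv_format_error("counts must be a non-empty taxa x samples matrix")
  taxa <- rownames(counts)
  samples <- colnames(counts)
  if (is.null(taxa) || is.null(samples))
    mv_format_error("counts must carry taxon row names and sample column names")
  if (anyDuplicated(taxa))
    mv_format_error(sprintf("duplicate taxon id: '%s'",
                            taxa[duplicated(taxa)][1L]))
  if (anyDuplicated(samples))
    mv_format_error(sprintf("duplicate sample id: '%s'",
                            samples[duplicated(samples)][1L]))
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != floor(counts),
                 arr.ind = TRUE)[1L, ]
    mv_format_error(sprintf(
      "count for taxon '%s', sample '%s' is not a non-negative integer",
      taxa[bad[1L]], samples[bad[2L]]))
  }
  if (is.null(taxonomy))
    taxonomy <- setNames(rep("unclassified", length(taxa)), taxa)
  missing_tax <- setdiff(taxa, names(taxonomy))
  if (length(missing_tax))
    mv_format_error(sprintf("no taxonomy entry for taxon '%s'", missing_tax[1L]))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, taxonomy = taxonomy[taxa]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d taxa x %d samples, %d genera\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$taxonomy))))
  invisible(x)
}

# Genus from a semicolon-delimited lineage: 6th rank if ranked, otherwise the
# whole string. A "g__" prefix is stripped; empty -> "unclassified".
parse_genus <- function(tax) {
  vapply(strsplit(tax, ";", fixed = TRUE), function(parts) {
    parts <- trimws(parts)
    g <- if (length(parts) >= 6L) parts[6L] else if (length(parts) == 1L) parts else ""
    g <- sub("^g__", "", g)
    if (!nzchar(g)) "unclassified" else g
  }, character(1L))
}

#' Read a feature table from TSV
#'
#' Reads a QIIME-classic style tab-separated table: taxa as rows, samples as
#' columns, leading header cell `#TaxonID` (the `biom_tsv` dialect instead
#' has a `# Constructed from biom file` comment line followed by an
#' `#OTU ID` header). An optional final `taxonomy` column holds
#' semicolon-delimited lineages, from which the genus (6th rank, or the
#' whole string if unranked) is extracted.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"biom_tsv"`.
#' @param taxonomy optional named character vector overriding the file's
#'   taxonomy column.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("tsv", "biom_tsv"),
                               taxonomy = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) mv_format_error(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  if (dialect == "biom_tsv" && length(lines) && startsWith(lines[1L], "# "))
    lines <- lines[-1L]
  if (length(lines) < 2L) mv_format_error(sprintf("empty feature table: '%s'", path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncol_expected <- length(header)
  bad_row <- which(vapply(body, length, integer(1L)) != ncol_expected)
  if (length(bad_row))
    mv_format_error(sprintf("row %d has %d fields, expected %d",
                            bad_row[1L] + 1L, length(body[[bad_row[1L]]]),
                            ncol_expected))
  has_tax <- tolower(header[ncol_expected]) == "taxonomy"
  sample_ids <- header[-c(1L, if (has_tax) ncol_expected)]
  taxa <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(taxa))
    mv_format_error(sprintf("duplicate taxon id: '%s'",
                            taxa[duplicated(taxa)][1L]))
  count_cols <- seq_along(header)[-c(1L, if (has_tax) ncol_expected)]
  counts <- matrix(NA_real_, length(taxa), length(sample_ids),
                   dimnames = list(taxa, sample_ids))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][count_cols]))
    bad <- which(is.na(vals) | vals < 0 | vals != floor(vals))
    if (length(bad))
      mv_format_error(sprintf(
        "count at row %d (taxon '%s'), column '%s' is not a non-negative integer: '%s'",
        i + 1L, taxa[i], sample_ids[bad[1L]], body[[i]][count_cols[bad[1L]]]))
    counts[i, ] <- vals
  }
  if (is.null(taxonomy) && has_tax) {
    lineages <- vapply(body, `[[`, character(1L), ncol_expected)
    taxonomy <- setNames(parse_genus(lineages), taxa)
  }
  feature_table(counts, taxonomy)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: the written file round-trips to an
#' identical `feature_table`. Genus labels are written in a final
#' `taxonomy` column.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param dialect `"tsv"` or `"biom_tsv"`.
#' @export
write_feature_table <- function(table, path, dialect = c("tsv", "biom_tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "feature_table"))
  header <- paste(c(if (dialect == "tsv") "#TaxonID" else "#OTU ID",
                    colnames(table$counts), "taxonomy"), collapse = "\t")
  rows <- vapply(seq_len(nrow(table$counts)), function(i) {
    paste(c(rownames(table$counts)[i], table$counts[i, ],
            unname(table$taxonomy[i])), collapse = "\t")
  }, character(1L))
  pre <- if (dialect == "biom_tsv") "# Constructed from biom file" else NULL
  writeLines(c(pre, header, rows), path)
  invisible(path)
}

#' Construct validated cohort metadata
#'
#' Cohort metadata binds each sample to its patient, body site and
#' collection time, and each patient to the clinical covariates and
#' outcomes used by the association screens. Missing clinical values are
#' allowed (`NA`); operations that need them fail loudly rather than
#' imputing.
#'
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `site` (`"oral"`/`"stool"`), `day` (integer, relative to chemotherapy
#'   start), `order` (positive collection index).
#' @param patients data.frame with columns `patient_id`, `age`,
#'   `days_all_abx`, `days_treatment_abx`, `n_antibiotics`,
#'   `pip_tazo_gt72h`, `cefepime_gt72h`, `carbapenem_gt72h`,
#'   `chemo_category`, `infection_during_ic`, `infection_90d_post`,
#'   `remission`.
#' @return Object of class `cohort_metadata`.
#' @export
cohort_metadata <- function(samples, patients) {
  miss <- setdiff(SAMPLE_COLUMNS, names(samples))
  if (length(miss))
    mv_format_error(sprintf("sample table missing column(s): %s",
                            paste(miss, collapse = ", ")))
  miss <- setdiff(PATIENT_COLUMNS, names(patients))
  if (length(miss))
    mv_format_error(sprintf("patient table missing column(s): %s",
                            paste(miss, collapse = ", ")))
  samples <- samples[SAMPLE_COLUMNS]
  patients <- patients[PATIENT_COLUMNS]
  if (anyDuplicated(samples$sample_id))
    mv_validation_error(sprintf("duplicate sample id: '%s'",
                                samples$sample_id[duplicated(samples$sample_id)][1L]))
  if (anyDuplicated(patients$patient_id))
    mv_validation_error(sprintf("duplicate patient id: '%s'",
                                patients$patient_id[duplicated(patients$patient_id)][1L]))
  unknown <- setdiff(samples$patient_id, patients$patient_id)
  if (length(unknown))
    mv_reference_error(sprintf(
      "sample(s) reference unknown patient '%s'", unknown[1L]))
  bad_site <- setdiff(unique(samples$site), SITE_LEVELS)
  if (length(bad_site))
    mv_validation_error(sprintf("unknown body site '%s'", bad_site[1L]))
  key <- paste(samples$patient_id, samples$site, samples$order, sep = "\r")
  if (anyDuplicated(key)) {
    d <- samples[duplicated(key), , drop = FALSE][1L, ]
    mv_validation_error(sprintf(
      "duplicate (patient, site, order) = ('%s', '%s', %s)",
      d$patient_id, d$site, d$order))
  }
  if (any(!is.finite(samples$day)))
    mv_validation_error("non-finite collection day")
  if (any(samples$order < 1 | samples$order != floor(samples$order)))
    mv_validation_error("collection order must be a positive integer")
  bad_chemo <- setdiff(stats::na.omit(unique(patients$chemo_category)), CHEMO_LEVELS)
  if (length(bad_chemo))
    mv_validation_error(sprintf("unknown chemo_category '%s'", bad_chemo[1L]))
  bad_inf <- setdiff(stats::na.omit(unique(patients$infection_during_ic)),
                     INFECTION_LEVELS)
  if (length(bad_inf))
    mv_validation_error(sprintf("unknown infection_during_ic '%s'", bad_inf[1L]))
  rownames(samples) <- NULL
  rownames(patients) <- NULL
  structure(list(samples = samples, patients = patients),
            class = "cohort_metadata")
}

#' @export
print.cohort_metadata <- function(x, ...) {
  cat(sprintf("cohort_metadata: %d samples, %d patients (%s)\n",
              nrow(x$samples), nrow(x$patients),
              paste(sprintf("%s: %d", SITE_LEVELS,
                            vapply(SITE_LEVELS, function(s)
                              sum(x$samples$site == s), integer(1L))),
                    collapse = ", ")))
  invisible(x)
}

#' Read sample and patient metadata
#'
#' Reads the two metadata TSVs and cross-validates them: every sample must
#' reference an existing patient and (patient, site, order) must be unique.
#'
#' @param sample_path TSV with columns `sample_id`, `patient_id`, `site`,
#'   `day`, `order`.
#' @param patient_path TSV with the patient-level clinical columns (see
#'   [cohort_metadata()]).
#' @return A [cohort_metadata()] object.
#' @export
read_metadata <- function(sample_path, patient_path) {
  for (p in c(sample_path, patient_path))
    if (!file.exists(p)) mv_format_error(sprintf("file not found: '%s'", p))
  samples <- read.delim(sample_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  patients <- read.delim(patient_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (col in c("pip_tazo_gt72h", "cefepime_gt72h", "carbapenem_gt72h",
                "infection_90d_post", "remission"))
    if (col %in% names(patients)) patients[[col]] <- as.logical(patients[[col]])
  cohort_metadata(samples, patients)
}

#' Write cohort metadata to the two-TSV layout read by [read_metadata()]
#' @param meta a [cohort_metadata()] object.
#' @param sample_path,patient_path output paths.
#' @export
write_metadata <- function(meta, sample_path, patient_path) {
  stopifnot(inherits(meta, "cohort_metadata"))
  write.table(meta$samples, sample_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(meta$patients, patient_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(sample_path, patient_path))
}

#' Construct a validated distance matrix
#'
#' @param values square numeric matrix, symmetric with zero diagonal, with
#'   identical row/column sample ids as dimnames.
#' @param tol symmetry tolerance.
#' @return Object of class `distance_matrix` (a labelled numeric matrix).
#' @export
distance_matrix <- function(values, tol = 1e-8) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    mv_format_error("distance matrix must be square")
  ids <- rownames(values)
  if (is.null(ids) || is.null(colnames(values)) ||
      !identical(ids, colnames(values)))
    mv_format_error("distance matrix must carry matching row/column ids")
  if (anyDuplicated(ids))
    mv_format_error(sprintf("duplicate sample id: '%s'", ids[duplicated(ids)][1L]))
  if (anyNA(values) || any(values < -tol))
    mv_format_error("distances must be non-negative")
  if (max(abs(values - t(values))) > tol)
    mv_format_error("distance matrix is not symmetric")
  if (any(abs(diag(values)) > tol))
    mv_format_error("distance matrix diagonal must be zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  values[values < 0] <- 0
  structure(values, class = c("distance_matrix", "matrix", "array"))
}

#' Read a square labelled distance matrix from TSV
#' @param path file path (first header cell is ignored; row and column
#'   labels must match).
#' @return A [distance_matrix()].
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) mv_format_error(sprintf("file not found: '%s'", path))
  df <- read.delim(path, check.names = FALSE, row.names = 1L)
  distance_matrix(as.matrix(df))
}

#' Write a distance matrix to TSV (round-trips within 1e-12)
#' @param dm a [distance_matrix()].
#' @param path output path.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  ids <- rownames(dm)
  header <- paste(c("sample_id", ids), collapse = "\t")
  rows <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], sprintf("%.17g", dm[i, ])), collapse = "\t"),
    character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
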