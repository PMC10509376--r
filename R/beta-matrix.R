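#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation beta values
#' (methylated fraction, in \[0, 1\]) with probes in rows and samples in
#' columns; row and column names carry the probe and sample identifiers.
#' This checks the container invariants: unique non-empty identifiers,
#' dimensions matching the identifier lists, and all values in \[0, 1\]
#' (within `tol`) or `NA`.
#'
#' @param beta Numeric matrix, probes x samples, with dimnames.
#' @param tol Numeric tolerance for boundary violations (default `1e-9`).
#' @return The validated matrix, invisibly, with any within-`tol` boundary
#'   excursions clamped to \[0, 1\].
#' @export
validate_beta_matrix <- function(beta, tol = 1e-9) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort_validation("`beta` must be a numeric matrix (probes x samples).")
  }
  pid <- rownames(beta)
  sid <- colnames(beta)
  if (is.null(pid) || is.null(sid) || any(!nzchar(pid)) || any(!nzchar(sid))) {
    abort_validation("`beta` must carry probe ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(pid)) {
    abort_validation(paste0("Duplicate probe ids: ",
                            paste(unique(pid[duplicated(pid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    abort_validation(paste0("Duplicate sample ids: ",
                            paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  bad <- which(!is.na(beta) & (beta < -tol | beta > 1 + tol), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort_data(sprintf(
      "Beta value out of [0, 1]: probe %s, sample %s, value %g (%d offending cell(s)).",
      pid[i], sid[j], beta[i, j], nrow(bad)))
  }
  beta[!is.na(beta) & beta < 0] <- 0
  beta[!is.na(beta) & beta > 1] <- 1
  invisible(beta)
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA", "NaN"))
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from delimited text
#'
#' Reads a TSV/CSV file (delimiter inferred from the extension) with one
#' header row and identifiers in the first column, as shipped in GEO series
#' matrices. The internal canonical orientation is probes x samples;
#' `orientation = "samples_in_rows"` transposes on ingest.
#'
#' @param path Path to a delimited text file.
#' @param orientation Either `"probes_in_rows"` (default) or
#'   `"samples_in_rows"`.
#' @return A validated probes x samples numeric matrix.
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- read_delim_quiet(path, guess_delim(path))
  if (ncol(df) < 2) abort_data("Beta matrix file needs an id column plus data columns.")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix to delimited text
#'
#' Values are written at full double precision so that a
#' write/read round-trip is lossless.
#'
#' @param beta Probes x samples beta matrix.
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  beta <- validate_beta_matrix(beta)
  df <- tibble::as_tibble(beta, rownames = "probe_id")
  readr::write_delim(df, path, delim = guess_delim(path), progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects a delimited file with at least a `sample_id` column; typical
#' additional columns are `condition` (class label), `reported_sex`
#' (`XX`/`XY`/`unknown`), `gestational_age` (weeks) and `batch_id`.
#'
#' @param path Path to TSV/CSV.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_quiet(path, guess_delim(path))
  if (!"sample_id" %in% names(df)) abort_data("Sample sheet must have a `sample_id` column.")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort_validation("Duplicate sample_id in sample sheet.")
  tibble::as_tibble(df)
}

#' Read a probe annotation table
#'
#' Expects columns `probe_id`, `chromosome`, `design_type` (`I`/`II`),
#' optional logical flag columns (`cross_hybridizing`, `polymorphic`,
#' `snp_probe`, `reference_nonvariable`) and a `platforms` column listing
#' platform membership as a comma- or semicolon-separated string
#' (e.g. `"HM450K,EPIC"`).
#'
#' @param path Path to TSV/CSV.
#' @return A tibble, one row per probe.
#' @export
read_probe_annotation <- function(path) {
  df <- read_delim_quiet(path, guess_delim(path))
  if (!"probe_id" %in% names(df)) abort_data("Annotation must have a `probe_id` column.")
  df$probe_id <- as.character(df$probe_id)
  if (anyDuplicated(df$probe_id)) abort_validation("Duplicate probe_id in annotation.")
  for (fl in c("cross_hybridizing", "polymorphic", "snp_probe", "reference_nonvariable")) {
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  }
  tibble::as_tibble(df)
}

platform_members <- function(platforms) {
  strsplit(as.character(platforms), "[,;]\\s*")
}

#' Restrict a beta matrix to probes shared by HM450K and EPIC
#'
#' Keeps only probes whose annotated `platforms` include both `HM450K` and
#' `EPIC`, preserving the input probe order. Training on the platform
#' intersection lets a classifier fitted on HM450K data be applied to EPIC
#' data later.
#'
#' @param beta Probes x samples beta matrix.
#' @param annotation Probe annotation tibble with `probe_id` and `platforms`.
#' @return The beta matrix restricted to shared probes.
#' @export
harmonize_platform <- function(beta, annotation) {
  beta <- validate_beta_matrix(beta)
  missing <- setdiff(rownames(beta), annotation$probe_id)
  if (length(missing) > 0) {
    abort_data(sprintf("Annotation does not cover %d probe(s), e.g. %s.",
                       length(missing), missing[1]))
  }
  members <- platform_members(annotation$platforms)
  shared <- annotation$probe_id[vapply(
    members, function(p) all(c("HM450K", "EPIC") %in% p), logical(1))]
  keep <- rownames(beta) %in% shared
  if (!any(keep)) abort_data("No probes shared between HM450K and EPIC.")
  beta[keep, , drop = FALSE]
}

#' Align a beta matrix with a sample sheet
#'
#' Restricts both to the intersection of sample ids, in the beta matrix's
#' column order, and reorders the sheet to match. Dropped samples are
#' reported with a warning.
#'
#' @param beta Probes x samples beta matrix.
#' @param sheet Sample sheet tibble with `sample_id`.
#' @return A list with elements `beta` and `sheet`, column-aligned.
#' @export
align_samples <- function(beta, sheet) {
  beta <- validate_beta_matrix(beta)
  common <- intersect(colnames(beta), sheet$sample_id)
  if (length(common) == 0) abort_data("No samples shared between beta matrix and sample sheet.")
  dropped <- setdiff(union(colnames(beta), sheet$sample_id), common)
  if (length(dropped) > 0) {
    rlang::warn(sprintf("Dropping %d unmatched sample(s): %s",
                        length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- colnames(beta)[colnames(beta) %in% common]
  list(beta = beta[, keep, drop = FALSE],
       sheet = sheet[match(keep, sheet$sample_id), , drop = FALSE])
}

#' Mean-impute missing beta values
#'
#' Replaces `NA` cells by the probe's (row) mean across samples. Modelling
#' operations in this package require complete data; imputation is explicit
#' and announced with a message so its use is auditable.
#'
#' @param beta Probes x samples beta matrix, possibly with `NA`s.
#' @return A complete beta matrix.
#' @export
impute_missing <- function(beta) {
  beta <- validate_beta_matrix(beta)
  n_na <- sum(is.na(beta))
  if (n_na == 0) return(beta)
  rm <- rowMeans(beta, na.rm = TRUE)
  if (anyNA(rm)) abort_data("Some probes have no observed values; cannot impute.")
  idx <- which(is.na(beta), arr.ind = TRUE)
  beta[idx] <- rm[idx[, 1]]
  rlang::inform(sprintf("Imputed %d missing beta value(s) by probe means.", n_na))
  beta
}
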