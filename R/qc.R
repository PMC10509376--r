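# Sample- and probe-level quality control for methylation beta matrices.
#
# Every check returns a tibble of "QC decisions" with a common shape so that
# reports are machine-readable:
#   unit_id, check, metric, threshold, flagged
# A unit is flagged iff its metric violates the threshold in the check's
# stated direction.

qc_decision <- function(unit_id, check, metric, threshold, flagged) {
  tibble::tibble(unit_id = as.character(unit_id), check = check,
                 metric = as.numeric(metric), threshold = as.numeric(threshold),
                 flagged = as.logical(flagged))
}

#' Mean inter-array correlation check
#'
#' For each sample, computes the mean Pearson correlation of its beta
#' profile against every other sample; samples whose mean correlation falls
#' below `threshold` (default 0.95) are flagged. Because clean methylomes
#' share a strongly bimodal probe-mean structure, genuine arrays correlate
#' highly and outliers (swaps, failed hybridizations) stand out.
#'
#' For speed on full-size arrays the metric is computed on a deterministic
#' subsample of up to `max_probes` most-variable probes (ties broken by row
#' order); set `max_probes = Inf` for full-probe mode.
#'
#' @param beta Probes x samples beta matrix (complete on the probes used).
#' @param threshold Flag samples with mean correlation below this (0.95).
#' @param max_probes Cap on probes used for the correlation (50,000).
#' @return A tibble of QC decisions, one row per sample.
#' @export
interarray_correlation_check <- function(beta, threshold = 0.95, max_probes = 50000) {
  beta <- validate_beta_matrix(beta)
  n <- ncol(beta)
  if (n < 3) abort_validation("Need >= 3 samples for the inter-array correlation screen.")
  if (nrow(beta) > max_probes) {
    v <- apply(beta, 1, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(max_probes)]
    beta <- beta[sort(keep), , drop = FALSE]
  }
  cc <- stats::cor(beta, use = "pairwise.complete.obs")
  mean_cor <- (rowSums(cc) - 1) / (n - 1)
  qc_decision(colnames(beta), "interarray_correlation", mean_cor, threshold,
              mean_cor < threshold)
}

#' Sex concordance check
#'
#' Infers chromosomal sex from per-sample median log2 total intensities on
#' chrX and chrY probes: samples are split into two clusters on the chrY
#' summary (2-means; the higher-intensity cluster is called XY) and the
#' call is cross-checked against chrX (the XX cluster should have the
#' higher chrX intensity). When the chrY summaries do not separate into two
#' clusters (all samples one sex), a fixed intensity cutpoint
#' `fallback_cutpoint` is used instead and the fallback is announced.
#' A sample is flagged iff inferred and reported sex disagree and the
#' reported sex is not `"unknown"`.
#'
#' @param xy_intensity Tibble with columns `sample_id`, `chrx`, `chry`
#'   (median log2 total intensity over chrX / chrY probes).
#' @param sheet Sample sheet tibble with `sample_id` and `reported_sex`.
#' @param min_separation Minimum chrY cluster-centre separation (log2
#'   units) for the 2-means split to be trusted (default 1).
#' @param fallback_cutpoint chrY cutpoint used when clustering degenerates
#'   (default 10.5; above is called XY).
#' @return A tibble of QC decisions; `metric` is the chrY summary and
#'   `threshold` the cluster boundary (or fallback cutpoint) used.
#' @export
sex_concordance_check <- function(xy_intensity, sheet,
                                  min_separation = 1, fallback_cutpoint = 10.5) {
  if (is.null(xy_intensity)) {
    rlang::warn("xy_intensity not supplied: sex concordance check skipped.")
    return(qc_decision(character(), "sex_concordance", numeric(), numeric(), logical()))
  }
  m <- dplyr::inner_join(xy_intensity, sheet[, c("sample_id", "reported_sex")],
                         by = "sample_id")
  chry <- m$chry
  boundary <- fallback_cutpoint
  use_fallback <- length(unique(chry)) < 2
  if (!use_fallback) {
    km <- stats::kmeans(chry, centers = range(chry))
    if (abs(diff(km$centers)) < min_separation) use_fallback <- TRUE else {
      boundary <- mean(km$centers)
    }
  }
  if (use_fallback) {
    rlang::inform(sprintf(
      "chrY intensities form a single cluster; using fixed cutpoint %.1f.",
      fallback_cutpoint))
  }
  inferred <- ifelse(chry > boundary, "XY", "XX")
  if (all(c("XX", "XY") %in% inferred)) {
    if (mean(m$chrx[inferred == "XX"]) <= mean(m$chrx[inferred == "XY"])) {
      rlang::warn("chrX intensities do not confirm the chrY clustering; calls may be unreliable.")
    }
  }
  flag <- inferred != m$reported_sex & m$reported_sex != "unknown"
  out <- qc_decision(m$sample_id, "sex_concordance", chry, boundary, flag)
  out$inferred_sex <- inferred
  out$reported_sex <- m$reported_sex
  out
}

#' SNP-probe contamination check
#'
#' Methylation arrays carry dozens of SNP (rs) probes whose betas cluster
#' at three genotype states. A contaminated sample (a mixture of two
#' individuals) produces intermediate allelic ratios. The score is the mean
#' absolute deviation of each SNP beta from the nearest of three genotype
#' centres estimated by 3-means over the pooled SNP betas (fixed centres
#' 0.12/0.50/0.88 when clustering degenerates); a sample is flagged iff its
#' score exceeds `score_threshold`. This nearest-centre deviation is a
#' deliberate simplification of likelihood-based outlier metrics; the
#' default threshold 0.12 leaves clean three-cluster data scoring < 0.05.
#'
#' @param snp_betas SNP-probe x sample beta matrix.
#' @param score_threshold Flag samples scoring above this (default 0.12).
#' @param fallback_centers Genotype centres used if 3-means degenerates.
#' @param centers Fixed genotype centres; skips the 3-means estimate
#'   entirely when supplied.
#' @return A tibble of QC decisions, one row per sample.
#' @export
snp_contamination_check <- function(snp_betas, score_threshold = 0.12,
                                    fallback_centers = c(0.12, 0.50, 0.88),
                                    centers = NULL) {
  if (is.null(snp_betas)) {
    rlang::warn("snp_betas not supplied: SNP contamination check skipped.")
    return(qc_decision(character(), "snp_contamination", numeric(), numeric(), logical()))
  }
  if (nrow(snp_betas) < 10) {
    rlang::warn(sprintf("Only %d SNP probes; >= 10 recommended for a stable score.",
                        nrow(snp_betas)))
  }
  pooled <- as.numeric(snp_betas)
  if (is.null(centers)) centers <- tryCatch({
    km <- stats::kmeans(pooled, centers = matrix(fallback_centers, ncol = 1))
    cc <- sort(drop(km$centers))
    if (min(diff(cc)) < 0.1) fallback_centers else cc
  }, error = function(e) fallback_centers)
  score <- apply(snp_betas, 2, function(b) {
    mean(apply(abs(outer(b, centers, "-")), 1, min))
  })
  qc_decision(colnames(snp_betas), "snp_contamination", score, score_threshold,
              score > score_threshold)
}

#' Probe quality filter (detection p-value / bead count)
#'
#' A probe-sample observation fails iff its detection p-value exceeds
#' `p_threshold` or its bead count is below `bead_threshold`. A probe is
#' dropped iff its failure fraction is strictly greater than
#' `max_fail_fraction` ("more than 5% of samples"): a probe failing in
#' exactly 5 of 100 samples is kept, 6 of 100 is dropped.
#'
#' @param detection_p Probes x samples matrix of detection p-values, or NULL.
#' @param bead_count Probes x samples integer matrix of bead counts, or NULL.
#' @param p_threshold Detection p-value failure cutoff (default 0.01).
#' @param bead_threshold Minimum acceptable bead count (default 3).
#' @param max_fail_fraction Tolerated failure fraction (default 0.05, strict).
#' @return A tibble with `probe_id`, `n_fail`, `fail_fraction`, `dropped`.
#' @export
probe_quality_filter <- function(detection_p = NULL, bead_count = NULL,
                                 p_threshold = 0.01, bead_threshold = 3,
                                 max_fail_fraction = 0.05) {
  if (is.null(detection_p) && is.null(bead_count)) {
    abort_validation("Supply at least one of detection_p / bead_count.")
  }
  if (!is.null(detection_p) && !is.null(bead_count) &&
      !identical(dim(detection_p), dim(bead_count))) {
    abort_validation("detection_p and bead_count must have identical dimensions.")
  }
  ref <- detection_p %||% bead_count
  fail <- matrix(FALSE, nrow(ref), ncol(ref))
  if (!is.null(detection_p)) fail <- fail | (detection_p > p_threshold)
  if (!is.null(bead_count)) fail <- fail | (bead_count < bead_threshold)
  n_fail <- rowSums(fail)
  frac <- n_fail / ncol(ref)
  tibble::tibble(probe_id = rownames(ref) %||% as.character(seq_len(nrow(ref))),
                 n_fail = as.integer(n_fail),
                 fail_fraction = frac,
                 dropped = frac > max_fail_fraction)
}

#' Blocklist probe filter
#'
#' Drops the union of probes carrying any of the `drop_flags` annotation
#' flags (cross-hybridizing, polymorphic, ...) or located on a dropped
#' chromosome (chrX/chrY by default).
#'
#' @param annotation Probe annotation tibble.
#' @param probes Probe ids to evaluate; defaults to all annotated probes.
#' @param drop_flags Flag columns whose TRUE entries are dropped.
#' @param drop_chromosomes Chromosomes whose probes are dropped.
#' @param missing_action `"error"` (default) if a probe is absent from the
#'   annotation, or `"keep"` to retain it with a warning.
#' @return A tibble with `probe_id`, `dropped`, `reason` (comma-joined).
#' @export
blocklist_filter <- function(annotation, probes = NULL,
                             drop_flags = c("cross_hybridizing", "polymorphic"),
                             drop_chromosomes = c("chrX", "chrY"),
                             missing_action = c("error", "keep")) {
  missing_action <- match.arg(missing_action)
  probes <- probes %||% annotation$probe_id
  missing <- setdiff(probes, annotation$probe_id)
  if (length(missing) > 0) {
    if (missing_action == "error") {
      abort_data(sprintf("%d probe(s) absent from annotation, e.g. %s.",
                         length(missing), missing[1]))
    }
    rlang::warn(sprintf("%d unannotated probe(s) kept.", length(missing)))
  }
  ann <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
  reasons <- vector("list", length(probes))
  for (fl in drop_flags) {
    if (!fl %in% names(ann)) next
    hit <- which(!is.na(ann[[fl]]) & ann[[fl]])
    for (i in hit) reasons[[i]] <- c(reasons[[i]], fl)
  }
  if ("chromosome" %in% names(ann)) {
    hit <- which(ann$chromosome %in% drop_chromosomes)
    for (i in hit) reasons[[i]] <- c(reasons[[i]], paste0("chromosome:", ann$chromosome[i]))
  }
  tibble::tibble(
    probe_id = probes,
    dropped = lengths(reasons) > 0,
    reason = vapply(reasons, function(r) paste(r, collapse = ","), character(1)))
}

#' Non-variable probe filter
#'
#' Drops probes that are non-variable in this dataset (inter-quantile beta
#' range, q90 - q10 by default, below `range_threshold`) AND carry the
#' external `reference_nonvariable` flag (e.g. reported non-variable in the
#' target tissue). Both conditions are required: a flat probe without the
#' reference flag is kept, as is a flagged probe that varies here.
#'
#' @param beta Probes x samples beta matrix (complete for tested probes).
#' @param annotation Probe annotation with `probe_id` and
#'   `reference_nonvariable`.
#' @param range_quantiles Lower/upper quantiles of the per-probe beta range
#'   (default `c(0.10, 0.90)`).
#' @param range_threshold Ranges below this count as non-variable (0.05).
#' @return A tibble with `probe_id`, `beta_range`, `reference_nonvariable`,
#'   `dropped`.
#' @export
nonvariable_filter <- function(beta, annotation,
                               range_quantiles = c(0.10, 0.90),
                               range_threshold = 0.05) {
  beta <- validate_beta_matrix(beta)
  qs <- t(apply(beta, 1, stats::quantile, probs = range_quantiles, names = FALSE))
  rng <- unname(qs[, 2] - qs[, 1])
  ref <- annotation$reference_nonvariable[match(rownames(beta), annotation$probe_id)]
  ref[is.na(ref)] <- FALSE
  tibble::tibble(probe_id = rownames(beta),
                 beta_range = rng,
                 reference_nonvariable = ref,
                 dropped = (rng < range_threshold) & ref)
}

#' Run the full QC pipeline on a cohort
#'
#' Applies the sample-level checks first (inter-array correlation, sex
#' concordance, SNP contamination; any failure removes the sample), then the
#' probe filters on the surviving samples in a fixed order: quality
#' (detection p / bead count) -> blocklist -> platform intersection ->
#' non-variable. Checks whose optional inputs are missing are skipped with
#' a logged warning, never silently passed.
#'
#' @param beta Probes x samples beta matrix.
#' @param sheet Sample sheet tibble aligned to `beta`.
#' @param qc Optional list of QC matrices: `detection_p`, `bead_count`
#'   (probes x samples), `xy_intensity` (tibble), `snp_betas`
#'   (SNP-probe x sample matrix).
#' @param annotation Optional probe annotation tibble; enables the
#'   blocklist, platform-intersection and non-variable filters.
#' @param config Named list overriding check parameters:
#'   `interarray_threshold`, `snp_score_threshold`, `p_threshold`,
#'   `bead_threshold`, `max_fail_fraction`, `drop_flags`,
#'   `drop_chromosomes`, `range_quantiles`, `range_threshold`,
#'   `harmonize_platforms` (logical).
#' @return A list with `beta` and `sheet` (survivors), `report` (tibble of
#'   all QC decisions), `dropped_samples`, `dropped_probes`, and `log`
#'   (character vector of checks run/skipped).
#' @export
run_qc <- function(beta, sheet, qc = NULL, annotation = NULL, config = list()) {
  al <- align_samples(beta, sheet)
  beta <- al$beta; sheet <- al$sheet
  cfg <- utils::modifyList(list(
    interarray_threshold = 0.95, interarray_max_probes = 50000,
    snp_score_threshold = 0.12,
    p_threshold = 0.01, bead_threshold = 3, max_fail_fraction = 0.05,
    drop_flags = c("cross_hybridizing", "polymorphic"),
    drop_chromosomes = c("chrX", "chrY"),
    range_quantiles = c(0.10, 0.90), range_threshold = 0.05,
    harmonize_platforms = TRUE), config)
  report <- list()
  log <- character()

  # --- sample checks -------------------------------------------------------
  d <- interarray_correlation_check(beta, cfg$interarray_threshold,
                                    cfg$interarray_max_probes)
  report$interarray <- d
  log <- c(log, "interarray_correlation: run")
  if (!is.null(qc$xy_intensity)) {
    d2 <- sex_concordance_check(qc$xy_intensity, sheet)
    report$sex <- d2[, c("unit_id", "check", "metric", "threshold", "flagged")]
    log <- c(log, "sex_concordance: run")
  } else {
    rlang::warn("sex_concordance skipped: no xy_intensity supplied.")
    log <- c(log, "sex_concordance: skipped (no xy_intensity)")
  }
  if (!is.null(qc$snp_betas)) {
    report$snp <- snp_contamination_check(qc$snp_betas, cfg$snp_score_threshold)
    log <- c(log, "snp_contamination: run")
  } else {
    rlang::warn("snp_contamination skipped: no snp_betas supplied.")
    log <- c(log, "snp_contamination: skipped (no snp_betas)")
  }
  sample_report <- dplyr::bind_rows(report)
  bad_samples <- unique(sample_report$unit_id[sample_report$flagged])
  keep_samples <- setdiff(colnames(beta), bad_samples)
  if (length(keep_samples) == 0) abort_data("All samples flagged by QC.")
  beta <- beta[, keep_samples, drop = FALSE]
  sheet <- sheet[sheet$sample_id %in% keep_samples, , drop = FALSE]

  # --- probe filters, on surviving samples --------------------------------
  probe_report <- list()
  dropped_probes <- character()
  if (!is.null(qc$detection_p) || !is.null(qc$bead_count)) {
    sub <- function(m) if (is.null(m)) NULL else m[, keep_samples, drop = FALSE]
    pq <- probe_quality_filter(sub(qc$detection_p), sub(qc$bead_count),
                               cfg$p_threshold, cfg$bead_threshold,
                               cfg$max_fail_fraction)
    probe_report$quality <- qc_decision(pq$probe_id, "probe_quality",
                                        pq$fail_fraction, cfg$max_fail_fraction,
                                        pq$dropped)
    dropped_probes <- union(dropped_probes, pq$probe_id[pq$dropped])
    log <- c(log, "probe_quality: run")
  } else {
    log <- c(log, "probe_quality: skipped (no detection_p/bead_count)")
  }
  beta <- beta[!rownames(beta) %in% dropped_probes, , drop = FALSE]

  if (!is.null(annotation)) {
    bl <- blocklist_filter(annotation, rownames(beta), cfg$drop_flags,
                           cfg$drop_chromosomes)
    probe_report$blocklist <- qc_decision(bl$probe_id, "blocklist",
                                          as.numeric(bl$dropped), 0.5, bl$dropped)
    dropped_probes <- union(dropped_probes, bl$probe_id[bl$dropped])
    beta <- beta[!rownames(beta) %in% bl$probe_id[bl$dropped], , drop = FALSE]
    log <- c(log, "blocklist: run")

    if (isTRUE(cfg$harmonize_platforms) && "platforms" %in% names(annotation)) {
      before <- rownames(beta)
      beta <- harmonize_platform(beta, annotation)
      gone <- setdiff(before, rownames(beta))
      probe_report$platform <- qc_decision(before, "platform_intersection",
                                           as.numeric(before %in% gone), 0.5,
                                           before %in% gone)
      dropped_probes <- union(dropped_probes, gone)
      log <- c(log, "platform_intersection: run")
    } else log <- c(log, "platform_intersection: skipped")

    if ("reference_nonvariable" %in% names(annotation)) {
      nv <- nonvariable_filter(beta, annotation, cfg$range_quantiles,
                               cfg$range_threshold)
      probe_report$nonvariable <- qc_decision(nv$probe_id, "nonvariable",
                                              nv$beta_range, cfg$range_threshold,
                                              nv$dropped)
      dropped_probes <- union(dropped_probes, nv$probe_id[nv$dropped])
      beta <- beta[!rownames(beta) %in% nv$probe_id[nv$dropped], , drop = FALSE]
      log <- c(log, "nonvariable: run")
    } else log <- c(log, "nonvariable: skipped (no reference_nonvariable flag)")
  } else {
    log <- c(log, "blocklist/platform/nonvariable: skipped (no annotation)")
  }

  list(beta = beta, sheet = sheet,
       report = dplyr::bind_rows(c(report, probe_report)),
       dropped_samples = bad_samples,
       dropped_probes = dropped_probes,
       log = log)
}

#' Write a QC report
#'
#' @param report QC decision tibble (from [run_qc()] or a single check).
#' @param path Output path; `.json` writes JSON, anything else a flat TSV.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(report, path, progress = FALSE)
  }
  invisible(path)
}
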