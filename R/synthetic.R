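# Seeded generator of synthetic methylation cohorts.
#
# The generator emulates the statistical structure the pipeline assumes: a
# two-class cohort (EOPE vs nPTB placentas by default) measured on a
# methylation array, with a planted sparse CpG signature, beta-distributed
# measurement noise with a common precision, probe-design (type I/II)
# distributional differences, optional logit-scale batch shifts, and
# optionally planted QC failures. Everything is driven by one seed and a
# truth record lists every planted quantity, so recovery tests downstream
# consume only the truth record.

#' Specify a synthetic methylation cohort
#'
#' The defaults describe the reference simulated cohort used throughout the
#' package's tests: 42 + 41 samples, 5,045 probes of which 45 form a
#' discriminative signature with class means 0.47 (EOPE, the
#' lower-methylation class) and 0.61 (nPTB), beta noise with precision
#' `phi = 60` (per-value variance `mu (1 - mu) / (1 + phi)`, i.e. sd ~0.064
#' at mu = 0.5, making the planted 0.14 difference a ~2 sd per-CpG effect),
#' 70% type II probes whose betas are compressed toward 0.5 by a factor
#' 0.8, and no batch shifts or planted QC failures. Background per-probe
#' means are drawn U-shaped (scaled Beta(0.4, 0.4)) over
#' `background_mean_range`, emulating the bimodal methylome of real
#' tissue. Signature probes are assigned design type I so that the planted
#' class means are stated on the output scale.
#'
#' @param n_per_class Named pair of class sizes (default
#'   `c(EOPE = 42, nPTB = 41)`); names become the condition labels.
#' @param n_probes Total probe count (default 5,045: 45 signature + 5,000
#'   background; a desk-scale stand-in for a full 341k-probe array).
#' @param n_signature Number of discriminative CpGs (default 45).
#' @param class_means Signature means per class, in `n_per_class` order
#'   (default `c(0.47, 0.61)`).
#' @param background_mean_range Range of background per-probe means
#'   (default `c(0.1, 0.9)`).
#' @param noise_precision Beta-distribution precision `phi` (default 60).
#' @param type2_fraction Fraction of background probes labelled design type
#'   II (default 0.7).
#' @param type2_compression Dilation of type II betas toward 0.5 (default
#'   0.8; 1 = no compression).
#' @param batch_spec Optional tibble/data.frame with columns `batch_id`,
#'   `logit_shift`, `n_samples`; samples are allocated to batches
#'   interleaved across conditions and shifted on the logit scale.
#' @param qc_failures Named list of planted failure counts:
#'   `contaminated` (samples with SNP betas uniform on (0.2, 0.8)),
#'   `sex_discordant` (samples whose chrX/chrY intensities are swapped to
#'   the opposite sex), `bad_probes` (probes with detection p > 0.01 in 10%
#'   of samples).
#' @param n_snp_probes Number of SNP (rs) probes simulated (default 59).
#' @param seed Integer seed; drives both the probe layout and the draws.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(EOPE = 42, nPTB = 41),
                           n_probes = 5045,
                           n_signature = 45,
                           class_means = c(0.47, 0.61),
                           background_mean_range = c(0.1, 0.9),
                           noise_precision = 60,
                           type2_fraction = 0.7,
                           type2_compression = 0.8,
                           batch_spec = NULL,
                           qc_failures = list(contaminated = 0,
                                              sex_discordant = 0,
                                              bad_probes = 0),
                           n_snp_probes = 59,
                           seed = 1) {
  if (is.null(names(n_per_class))) names(n_per_class) <- c("EOPE", "nPTB")
  stopifnot(length(n_per_class) == 2, length(class_means) == 2)
  if (any(class_means <= 0 | class_means >= 1)) {
    abort_validation("class_means must lie strictly inside (0, 1).")
  }
  if (noise_precision <= 0) abort_validation("noise_precision must be positive.")
  if (n_signature > n_probes) abort_validation("n_signature cannot exceed n_probes.")
  qc_failures <- utils::modifyList(
    list(contaminated = 0, sex_discordant = 0, bad_probes = 0), qc_failures)
  n_samples <- sum(n_per_class)
  if (qc_failures$contaminated + qc_failures$sex_discordant > n_samples) {
    abort_validation("More planted sample failures than samples.")
  }
  if (qc_failures$bad_probes > n_probes) {
    abort_validation("More planted bad probes than probes.")
  }
  structure(list(
    n_per_class = n_per_class, n_probes = as.integer(n_probes),
    n_signature = as.integer(n_signature), class_means = class_means,
    background_mean_range = background_mean_range,
    noise_precision = noise_precision, type2_fraction = type2_fraction,
    type2_compression = type2_compression, batch_spec = batch_spec,
    qc_failures = qc_failures, n_snp_probes = as.integer(n_snp_probes),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Probe layout (ids, signature positions, design types, background means)
# is a function of the spec seed alone, so training and validation cohorts
# generated from the same spec share it.
probe_layout <- function(spec) {
  with_seed(spec$seed, {
    probe_ids <- sprintf("cg%08d", seq_len(spec$n_probes))
    signature <- sort(sample.int(spec$n_probes, spec$n_signature))
    design <- ifelse(stats::runif(spec$n_probes) < spec$type2_fraction, "II", "I")
    design[signature] <- "I"
    r <- spec$background_mean_range
    mu <- r[1] + diff(r) * stats::rbeta(spec$n_probes, 0.4, 0.4)
    list(probe_ids = probe_ids, signature = signature, design = design,
         background_mu = mu)
  })
}

draw_betas <- function(mu_matrix, phi) {
  n <- length(mu_matrix)
  b <- stats::rbeta(n, mu_matrix * phi, (1 - mu_matrix) * phi)
  matrix(b, nrow = nrow(mu_matrix))
}

apply_logit_shift <- function(beta, shift) {
  stats::plogis(stats::qlogis(clip_unit(beta)) + shift)
}

generate_samples <- function(spec, layout, n_per_class, seed, shift = 0) {
  labels <- rep(names(n_per_class), n_per_class)
  n <- length(labels)
  with_seed(seed, {
    mu <- matrix(layout$background_mu, spec$n_probes, n)
    for (k in 1:2) {
      mu[layout$signature, labels == names(n_per_class)[k]] <- spec$class_means[k]
    }
    beta <- draw_betas(mu, spec$noise_precision)

    batch_id <- rep("batch1", n)
    if (!is.null(spec$batch_spec)) {
      bs <- spec$batch_spec
      if (sum(bs$n_samples) != n) abort_validation("batch_spec sample counts must sum to the cohort size.")
      alloc <- rep(seq_len(nrow(bs)), bs$n_samples)
      # walk samples alternating between classes so batch blocks are not
      # confounded with condition
      within_rank <- stats::ave(seq_len(n), labels, FUN = seq_along)
      ord <- order(within_rank, labels)
      batch_id[ord] <- as.character(bs$batch_id[alloc])
      for (i in seq_len(nrow(bs))) {
        cols <- which(batch_id == bs$batch_id[i])
        if (bs$logit_shift[i] != 0) {
          beta[, cols] <- apply_logit_shift(beta[, cols], bs$logit_shift[i])
        }
      }
    }
    if (shift != 0) beta <- apply_logit_shift(beta, shift)

    is2 <- layout$design == "II"
    beta[is2, ] <- 0.5 + spec$type2_compression * (beta[is2, ] - 0.5)
    beta <- pmin(pmax(beta, 0), 1)
    list(beta = beta, labels = labels, batch_id = batch_id)
  })
}

#' Generate a synthetic training cohort
#'
#' Draws a full cohort from a [synthetic_spec()]: beta matrix, sample
#' sheet, probe annotation, QC matrices, and a truth record listing the
#' signature probes, planted failures, and all generating parameters.
#' Output is byte-identical across runs for a fixed spec seed.
#'
#' @param spec A `synthetic_spec`.
#' @return A list: `beta` (probes x samples matrix), `sheet` (tibble),
#'   `annotation` (tibble), `qc` (list: `detection_p`, `bead_count`,
#'   `xy_intensity`, `snp_betas`), `truth` (list).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  layout <- probe_layout(spec)
  draw_seed <- derive_seed(spec$seed, 1)
  smp <- generate_samples(spec, layout, spec$n_per_class, draw_seed)
  n <- sum(spec$n_per_class)
  sample_ids <- sprintf("S%03d", seq_len(n))
  dimnames(smp$beta) <- list(layout$probe_ids, sample_ids)

  qcf <- spec$qc_failures
  with_seed(derive_seed(spec$seed, 2), {
    reported_sex <- rep_len(c("XX", "XY"), n)[sample.int(n)]
    ga_mean <- ifelse(smp$labels == names(spec$n_per_class)[1], 31.6, 33.8)
    gestational_age <- round(pmin(pmax(stats::rnorm(n, ga_mean, 2), 25), 39), 1)

    # chrX / chrY median log2 intensity summaries by true sex
    true_sex <- reported_sex
    discordant <- character(0)
    if (qcf$sex_discordant > 0) {
      discordant <- sample(sample_ids, qcf$sex_discordant)
      i <- match(discordant, sample_ids)
      true_sex[i] <- ifelse(reported_sex[i] == "XX", "XY", "XX")
    }
    chrx <- ifelse(true_sex == "XX", 13.2, 12.2) + stats::rnorm(n, 0, 0.1)
    chry <- ifelse(true_sex == "XX", 9.0, 12.8) + stats::rnorm(n, 0, 0.2)
    xy_intensity <- tibble::tibble(sample_id = sample_ids, chrx = chrx, chry = chry)

    # SNP (rs) probes: three genotype clusters; contaminated samples uniform
    geno_centers <- c(0.1, 0.5, 0.9)
    snp <- matrix(0, spec$n_snp_probes, n,
                  dimnames = list(sprintf("rs%07d", seq_len(spec$n_snp_probes)),
                                  sample_ids))
    for (j in seq_len(n)) {
      g <- sample(geno_centers, spec$n_snp_probes, replace = TRUE,
                  prob = c(0.3, 0.4, 0.3))
      snp[, j] <- clip_unit(g + stats::rnorm(spec$n_snp_probes, 0, 0.02), 0.001)
    }
    contaminated <- character(0)
    if (qcf$contaminated > 0) {
      contaminated <- sample(setdiff(sample_ids, discordant), qcf$contaminated)
      for (s in contaminated) {
        snp[, s] <- stats::runif(spec$n_snp_probes, 0.2, 0.8)
      }
    }

    # detection p / bead counts; planted bad probes fail in 10% of samples
    detection_p <- matrix(stats::runif(spec$n_probes * n, 0, 0.005),
                          spec$n_probes, n,
                          dimnames = list(layout$probe_ids, sample_ids))
    bead_count <- matrix(3L + stats::rpois(spec$n_probes * n, 10),
                         spec$n_probes, n,
                         dimnames = list(layout$probe_ids, sample_ids))
    bad_probes <- character(0)
    if (qcf$bad_probes > 0) {
      bad_idx <- sample(setdiff(seq_len(spec$n_probes), layout$signature),
                        qcf$bad_probes)
      bad_probes <- layout$probe_ids[bad_idx]
      n_fail <- max(ceiling(0.10 * n), floor(0.05 * n) + 1)
      for (i in bad_idx) {
        cols <- sample.int(n, n_fail)
        detection_p[i, cols] <- stats::runif(n_fail, 0.02, 0.5)
      }
    }
  })

  sheet <- tibble::tibble(sample_id = sample_ids,
                          condition = smp$labels,
                          reported_sex = reported_sex,
                          gestational_age = gestational_age,
                          batch_id = smp$batch_id)
  annotation <- tibble::tibble(
    probe_id = layout$probe_ids,
    chromosome = paste0("chr", rep_len(1:22, spec$n_probes)),
    design_type = layout$design,
    cross_hybridizing = FALSE, polymorphic = FALSE, snp_probe = FALSE,
    reference_nonvariable = FALSE,
    platforms = "HM450K,EPIC")

  truth <- list(signature_probes = layout$probe_ids[layout$signature],
                class_means = stats::setNames(spec$class_means,
                                              names(spec$n_per_class)),
                background_mu = stats::setNames(layout$background_mu,
                                                layout$probe_ids),
                design_type = stats::setNames(layout$design, layout$probe_ids),
                contaminated_samples = contaminated,
                sex_discordant_samples = discordant,
                bad_probes = bad_probes,
                spec = spec)

  list(beta = smp$beta, sheet = sheet, annotation = annotation,
       qc = list(detection_p = detection_p, bead_count = bead_count,
                 xy_intensity = xy_intensity, snp_betas = snp),
       truth = truth)
}

#' Generate an independent validation cohort
#'
#' Draws a fresh cohort from the same generative family as
#' [generate_cohort()] (same probe layout, signature and class means),
#' optionally applying a cohort-level logit-scale shift to all probes to
#' emulate a dataset effect between training and validation cohorts.
#'
#' @param spec The training `synthetic_spec`.
#' @param model_feature_ids Optional probe ids that must exist in the
#'   generated cohort (e.g. a fitted model's features); an error is raised
#'   if any are absent.
#' @param n_per_class Class sizes for the validation draw; defaults to the
#'   spec's.
#' @param cohort_shift Logit-scale shift applied to every probe (default 0).
#' @param seed Seed for the validation draw; defaults to a child of the
#'   spec seed distinct from the training draw.
#' @return A list: `beta`, `sheet`, `truth`.
#' @export
generate_validation_cohort <- function(spec, model_feature_ids = NULL,
                                       n_per_class = NULL, cohort_shift = 0,
                                       seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_per_class <- n_per_class %||% spec$n_per_class
  if (sum(n_per_class) == 0) abort_validation("Validation cohort must contain samples.")
  layout <- probe_layout(spec)
  if (!is.null(model_feature_ids)) {
    missing <- setdiff(model_feature_ids, layout$probe_ids)
    if (length(missing) > 0) {
      abort_data(sprintf("%d model feature(s) absent from the generated probes.",
                         length(missing)))
    }
  }
  seed <- seed %||% derive_seed(spec$seed, 99)
  smp <- generate_samples(spec, layout, n_per_class, seed, shift = cohort_shift)
  n <- sum(n_per_class)
  sample_ids <- sprintf("V%03d", seq_len(n))
  dimnames(smp$beta) <- list(layout$probe_ids, sample_ids)
  sheet <- tibble::tibble(sample_id = sample_ids, condition = smp$labels)
  list(beta = smp$beta, sheet = sheet,
       truth = list(signature_probes = layout$probe_ids[layout$signature],
                    cohort_shift = cohort_shift, seed = seed))
}
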