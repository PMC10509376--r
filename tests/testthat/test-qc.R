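test_that("inter-array correlation matches a brute-force pairwise mean", {
  beta <- make_beta(6, 4, seed = 1)
  d <- interarray_correlation_check(beta, threshold = 0.95)
  brute <- vapply(seq_len(4), function(j) {
    mean(vapply(setdiff(1:4, j), function(k) cor(beta[, j], beta[, k]), numeric(1)))
  }, numeric(1))
  expect_equal(d$metric, brute, tolerance = 1e-12)

  same <- make_beta(5, 3, values = rep(seq(0.1, 0.5, 0.1), 3))
  d2 <- interarray_correlation_check(same)
  expect_equal(d2$metric, rep(1, 3))
  expect_false(any(d2$flagged))
  expect_error(interarray_correlation_check(make_beta(5, 2)),
               class = "methylpls_validation_error")
})

test_that("a pure-noise array is the only sample flagged among coherent ones", {
  co <- small_cohort(n_probes = 5045, seed = 5)
  noise <- withr::with_seed(99, stats::runif(nrow(co$beta)))
  beta <- cbind(co$beta, NOISE = noise)
  d <- interarray_correlation_check(beta)
  expect_identical(d$unit_id[d$flagged], "NOISE")
})

test_that("sex concordance flags only reported/inferred mismatches", {
  xy <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:8),
    chrx = c(13.2, 13.1, 12.2, 12.3, 13.3, 12.1, 13.2, 12.2),
    chry = c(9.0, 9.1, 12.8, 12.7, 8.9, 12.9, 9.2, 12.6))
  truth_sex <- c("XX", "XX", "XY", "XY", "XX", "XY", "XX", "XY")
  sheet <- tibble::tibble(sample_id = xy$sample_id, reported_sex = truth_sex)
  d <- sex_concordance_check(xy, sheet)
  expect_false(any(d$flagged))

  sheet2 <- sheet
  sheet2$reported_sex[3] <- "XX"   # an XY-like sample reported as XX
  sheet2$reported_sex[1] <- "unknown"
  d2 <- sex_concordance_check(xy, sheet2)
  expect_identical(d2$unit_id[d2$flagged], "S03")

  # degenerate single-sex cohort falls back to the fixed cutpoint, loudly
  xx_only <- xy[c(1, 2, 5, 7), ]
  expect_message(
    d3 <- sex_concordance_check(xx_only, sheet[c(1, 2, 5, 7), ]),
    "cutpoint")
  expect_false(any(d3$flagged))

  expect_warning(d4 <- sex_concordance_check(NULL, sheet), "skipped")
  expect_equal(nrow(d4), 0)
})

test_that("SNP contamination score equals the nearest-centre deviation by hand", {
  centers <- c(0.12, 0.50, 0.88)
  b <- c(0.10, 0.52, 0.90, 0.30, 0.70)   # 5-SNP fixture
  snp <- matrix(rep(b, 2), ncol = 2,
                dimnames = list(paste0("rs", 1:5), c("A", "B")))
  expect_warning(d <- snp_contamination_check(snp, centers = centers),
                 "10 recommended")
  hand <- mean(vapply(b, function(x) min(abs(x - centers)), numeric(1)))
  expect_equal(d$metric, rep(hand, 2), tolerance = 1e-12)
})

test_that("contaminated samples score high; clean homozygous-only samples do not", {
  withr::local_seed(7)
  n_snp <- 59
  clean <- vapply(1:10, function(j) {
    g <- sample(c(0.05, 0.95), n_snp, replace = TRUE)
    pmin(pmax(g + rnorm(n_snp, 0, 0.02), 0.001), 0.999)
  }, numeric(n_snp))
  mixed <- runif(n_snp, 0.2, 0.8)
  snp <- cbind(clean, mixed)
  colnames(snp) <- c(sprintf("C%02d", 1:10), "MIX")
  rownames(snp) <- sprintf("rs%02d", 1:n_snp)
  d <- snp_contamination_check(snp)
  expect_identical(d$unit_id[d$flagged], "MIX")
  expect_true(all(d$metric[d$unit_id != "MIX"] < d$metric[d$unit_id == "MIX"]))
})

test_that("probe quality filter applies the strict >5% rule at the boundary", {
  dp <- matrix(0.001, 3, 100, dimnames = list(c("p6", "p5", "ok"), NULL))
  dp["p6", 1:6] <- 0.02    # 6/100 fail -> dropped
  dp["p5", 1:5] <- 0.02    # 5/100 fail -> kept (0.05 is not > 0.05)
  res <- probe_quality_filter(detection_p = dp)
  expect_identical(res$probe_id[res$dropped], "p6")

  bc <- matrix(10L, 2, 10)
  res2 <- probe_quality_filter(detection_p = matrix(0.001, 2, 10), bead_count = bc)
  expect_false(any(res2$dropped))

  # bead count and detection p combine with OR per observation
  bc[1, 1:2] <- 2L
  res3 <- probe_quality_filter(detection_p = matrix(0.001, 2, 10), bead_count = bc,
                               max_fail_fraction = 0.05)
  expect_identical(res3$dropped, c(TRUE, FALSE))
})

test_that("blocklist filter equals the brute-force union of per-criterion sets", {
  ann <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:10),
    chromosome = c(rep("chr1", 6), "chrX", "chrY", "chr2", "chr3"),
    cross_hybridizing = c(TRUE, rep(FALSE, 9)),
    polymorphic = c(FALSE, TRUE, TRUE, rep(FALSE, 7)))
  res <- blocklist_filter(ann)
  brute <- union(ann$probe_id[ann$cross_hybridizing | ann$polymorphic],
                 ann$probe_id[ann$chromosome %in% c("chrX", "chrY")])
  expect_setequal(res$probe_id[res$dropped], brute)
  expect_false(res$dropped[res$probe_id == "p09"])

  expect_error(blocklist_filter(ann, probes = c("p01", "zz")),
               class = "methylpls_data_error")
  expect_warning(res2 <- blocklist_filter(ann, probes = c("p01", "zz"),
                                          missing_action = "keep"), "unannotated")
  expect_false(res2$dropped[res2$probe_id == "zz"])
})

test_that("non-variable filter requires both the flat range and the reference flag", {
  beta <- rbind(
    flat_ref = rep(0.80, 10),
    flat_noref = rep(0.80, 10),
    var_ref = seq(0.2, 0.8, length.out = 10))
  colnames(beta) <- sprintf("S%02d", 1:10)
  ann <- tibble::tibble(probe_id = rownames(beta),
                        reference_nonvariable = c(TRUE, FALSE, TRUE))
  res <- nonvariable_filter(beta, ann)
  expect_identical(res$dropped, c(TRUE, FALSE, FALSE))
})

test_that("run_qc removes exactly the planted failures and composes its parts", {
  co <- small_cohort(n_probes = 1045, seed = 21,
                     qc_failures = list(contaminated = 1, sex_discordant = 1,
                                        bad_probes = 10))
  res <- suppressWarnings(run_qc(co$beta, co$sheet, co$qc, co$annotation))
  expect_setequal(res$dropped_samples,
                  c(co$truth$contaminated_samples, co$truth$sex_discordant_samples))
  expect_setequal(res$dropped_probes, co$truth$bad_probes)

  # composition oracle: sequential application of the individual filters
  keep_samples <- setdiff(colnames(co$beta), res$dropped_samples)
  pq <- probe_quality_filter(co$qc$detection_p[, keep_samples],
                             co$qc$bead_count[, keep_samples])
  expect_setequal(res$dropped_probes, pq$probe_id[pq$dropped])
  expect_equal(nrow(res$beta), nrow(co$beta) - length(res$dropped_probes))
  expect_equal(ncol(res$beta), ncol(co$beta) - length(res$dropped_samples))
})

test_that("run_qc on a clean cohort removes nothing and reports every check", {
  co <- small_cohort(n_probes = 545, seed = 31)
  res <- run_qc(co$beta, co$sheet, co$qc, co$annotation)
  expect_length(res$dropped_samples, 0)
  expect_length(res$dropped_probes, 0)
  expect_true(all(c("interarray_correlation: run", "sex_concordance: run",
                    "snp_contamination: run", "probe_quality: run",
                    "blocklist: run", "platform_intersection: run") %in% res$log))
  expect_true(all(c("unit_id", "check", "metric", "threshold", "flagged") %in%
                    names(res$report)))
})

test_that("run_qc survivors are invariant to input row/column order", {
  co <- small_cohort(n_probes = 545, seed = 41,
                     qc_failures = list(contaminated = 1, bad_probes = 3))
  res1 <- suppressWarnings(run_qc(co$beta, co$sheet, co$qc, co$annotation))
  perm_p <- withr::with_seed(1, sample(nrow(co$beta)))
  perm_s <- withr::with_seed(2, sample(ncol(co$beta)))
  qc2 <- co$qc
  qc2$detection_p <- qc2$detection_p[perm_p, perm_s]
  qc2$bead_count <- qc2$bead_count[perm_p, perm_s]
  qc2$snp_betas <- qc2$snp_betas[, perm_s]
  res2 <- suppressWarnings(run_qc(co$beta[perm_p, perm_s],
                                  co$sheet[perm_s, ], qc2, co$annotation))
  expect_setequal(rownames(res1$beta), rownames(res2$beta))
  expect_setequal(colnames(res1$beta), colnames(res2$beta))
})
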