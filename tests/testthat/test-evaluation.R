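test_that("stratified folds partition the cohort with balanced class counts", {
  labels <- rep(c("EOPE", "nPTB"), each = 42)   # 84 balanced samples
  folds <- stratified_folds(labels, M = 3, repeats = 4, seed = 7)
  for (r in 1:4) {
    fr <- folds[folds$repeat_id == r, ]
    expect_setequal(fr$index, 1:84)
    counts <- table(fr$fold, labels[fr$index])
    expect_true(all(counts == 14))           # three folds of 28, 14 per class
  }
  # same seed -> identical; different seeds differ (checked over 10 seeds)
  f1 <- stratified_folds(labels, M = 3, repeats = 2, seed = 5)
  expect_identical(stratified_folds(labels, M = 3, repeats = 2, seed = 5), f1)
  others <- vapply(1:10, function(s) {
    identical(stratified_folds(labels, M = 3, repeats = 2, seed = 100 + s), f1)
  }, logical(1))
  expect_false(any(others))
  expect_error(stratified_folds(c("a", "a", "b"), M = 3),
               class = "methylpls_validation_error")
})

test_that("error rates match hand counts, overall and per class", {
  truth <- rep(c("pos", "neg"), each = 5)
  calls <- truth
  calls[1] <- "neg"; calls[6] <- "pos"        # 2 wrong of 10, one per class
  oer <- compute_oer(calls, truth)
  expect_equal(oer$overall, 0.2)
  expect_equal(unname(oer$per_class[c("pos", "neg")]), c(0.2, 0.2))
  expect_equal(compute_oer(truth, truth)$overall, 0)
})

test_that("AUC equals brute-force pairwise counting, with ties at one half", {
  brute_auc <- function(p, y, pos = "p") {
    pairs <- expand.grid(i = which(y == pos), j = which(y != pos))
    mean(ifelse(p[pairs$i] > p[pairs$j], 1, ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
  }
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p"), 1)
  p2 <- c(0.9, 0.4, 0.6, 0.2); y2 <- c("p", "n", "n", "p")
  expect_equal(compute_auc(p2, y2, "p"), 0.5)
  expect_equal(compute_auc(p2, y2, "p"), brute_auc(p2, y2))
  expect_equal(compute_auc(rep(0.5, 6), rep(c("p", "n"), 3), "p"), 0.5)
  withr::with_seed(13, for (i in 1:5) {
    p <- round(runif(12), 1)                  # rounding forces ties
    y <- sample(rep(c("p", "n"), 6))
    expect_equal(compute_auc(p, y, "p"), brute_auc(p, y))
  })
  expect_error(compute_auc(c(0.1, 0.2), c("p", "p"), "p"),
               class = "methylpls_validation_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(17)
  p <- runif(40); y <- sample(rep(c("p", "n"), 20))
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, p, levels = c("n", "p"),
                                                         direction = "<"))))
  expect_equal(compute_auc(p, y, "p"), ref, tolerance = 1e-12)
})

test_that("Brier score follows its closed forms and conventions", {
  expect_equal(compute_brier(c(1, 1, 0, 0), c("p", "p", "n", "n"), "p"), 0)
  expect_equal(compute_brier(rep(0.5, 4), c("p", "p", "n", "n"), "p"), 0.25)
  p <- c(0.8, 0.3, 0.6, 0.1); y <- c("p", "p", "n", "n")
  hand <- mean(c((0.8 - 1)^2, (0.3 - 1)^2, (0.6 - 0)^2, (0.1 - 0)^2))
  expect_equal(compute_brier(p, y, "p"), hand)
  expect_equal(compute_brier(p, y, "p", convention = "multiclass"), 2 * hand)
})

test_that("Youden threshold maximizes J against exhaustive enumeration", {
  p <- c(0.05, 0.2, 0.3, 0.45, 0.5, 0.55, 0.6, 0.7, 0.9, 0.95)
  y <- c("n", "n", "n", "p", "n", "p", "n", "p", "p", "p")
  res <- youden_threshold(p, y, "p")
  # brute force over a fine threshold grid
  grid <- seq(0, 1, by = 0.001)
  js <- vapply(grid, function(t) {
    cm <- confusion_metrics(ifelse(p >= t, "p", "n"), y, "p")
    cm$sensitivity + cm$specificity - 1
  }, numeric(1))
  expect_equal(res$j, max(js), tolerance = 1e-9)
  expect_equal(res$threshold,
               min(res$roc$threshold[res$roc$j >= max(res$roc$j) - 1e-12]))
  expect_true(all(diff(res$roc$sensitivity) <= 1e-12))
  expect_equal(0.60 + 0.91 - 1, 0.51, tolerance = 1e-12)

  sep <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c("n", "n", "p", "p"), "p")
  expect_equal(sep$j, 1)
  expect_equal(sep$threshold, 0.5)
})

test_that("confusion metrics reproduce the validation-style worked counts", {
  calls <- c(rep("EOPE", 23), rep("nPTB", 15), rep("nPTB", 10), "EOPE")
  truth <- c(rep("EOPE", 38), rep("nPTB", 11))
  cm <- confusion_metrics(calls, truth, "EOPE")
  expect_equal(cm$tp, 23); expect_equal(cm$fn, 15)
  expect_equal(cm$tn, 10); expect_equal(cm$fp, 1)
  expect_equal(cm$sensitivity, 23 / 38)
  expect_equal(cm$specificity, 10 / 11)
  all_right <- confusion_metrics(truth, truth, "EOPE")
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
})

test_that("signature delta-beta matches brute-force averaging", {
  beta <- make_beta(3, 4, values = c(0.2, 0.4, 0.6,  0.3, 0.5, 0.7,
                                     0.6, 0.8, 0.9,  0.7, 0.9, 0.8))
  labels <- c("g1", "g1", "g2", "g2")
  res <- signature_delta_beta(beta, labels, rownames(beta))
  expect_equal(unname(res$group_means["g1"]), mean(beta[, 1:2]))
  expect_equal(unname(res$group_means["g2"]), mean(beta[, 3:4]))
  expect_equal(res$delta_beta, abs(mean(beta[, 1:2]) - mean(beta[, 3:4])))
  dup <- beta[, c(1, 2, 1, 2)]
  colnames(dup) <- paste0("S", 1:4)
  same <- signature_delta_beta(dup, labels, rownames(beta))
  expect_equal(same$delta_beta, 0)
})

test_that("cross-validation aggregates are recomputable from per-fold records", {
  co <- small_cohort(n_probes = 245, seed = 111)
  rep <- cross_validate(t(co$beta), co$sheet$condition, keepX_grid = c(45, 10),
                        M = 3, repeats = 3, seed = 77)
  # every repeat partitions the cohort exactly
  for (r in 1:3) {
    fr <- rep$folds[rep$folds$repeat_id == r, ]
    expect_setequal(fr$index, seq_len(ncol(co$beta)))
  }
  # recompute OER/AUC/Brier for keepX = 45 from the stored predictions
  pr <- rep$predictions[rep$predictions$keepX == 45, ]
  by_rep <- split(pr, pr$repeat_id)
  oer <- mean(vapply(by_rep, function(d) mean(d$call_max != d$truth), numeric(1)))
  auc <- mean(vapply(by_rep, function(d) compute_auc(d$prob_pos, d$truth, "EOPE"),
                     numeric(1)))
  brier <- mean(vapply(by_rep, function(d) compute_brier(d$prob_pos, d$truth, "EOPE"),
                       numeric(1)))
  m45 <- rep$metrics[rep$metrics$keepX == 45, ]
  expect_equal(m45$oer, oer, tolerance = 1e-12)
  expect_equal(m45$auc, auc, tolerance = 1e-12)
  expect_equal(m45$brier, brier, tolerance = 1e-12)
})

test_that("held-out labels cannot leak into cross-validated predictions", {
  co <- small_cohort(n_probes = 245, seed = 121)
  X <- t(co$beta); y <- co$sheet$condition
  folds <- stratified_folds(y, M = 3, repeats = 1, seed = 31)
  base <- cross_validate(X, y, keepX_grid = 20, folds = folds,
                         class_labels = c("EOPE", "nPTB"))
  for (f in 1:3) {
    test_idx <- folds$index[folds$fold == f]
    y_corrupt <- y
    y_corrupt[test_idx] <- withr::with_seed(f, sample(y[test_idx]))
    alt <- cross_validate(X, y_corrupt, keepX_grid = 20, folds = folds,
                          class_labels = c("EOPE", "nPTB"))
    b <- base$predictions[base$predictions$fold == f, ]
    a <- alt$predictions[alt$predictions$fold == f, ]
    expect_equal(a$prob_pos[order(a$sample_id)], b$prob_pos[order(b$sample_id)],
                 tolerance = 1e-12, info = paste("fold", f))
  }
})

test_that("feature stability hits 1 for always-selected and 0 for never-selected probes", {
  co <- small_cohort(n_probes = 245, seed = 131)
  rep <- cross_validate(t(co$beta), co$sheet$condition, keepX_grid = 45,
                        M = 3, repeats = 5, seed = 41)
  st <- feature_stability(rep, 45, feature_ids = rownames(co$beta))
  planted <- co$truth$signature_probes
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  expect_true(mean(st$frequency[st$probe_id %in% planted] >= 0.5) >= 0.9)
  expect_true(all(st$frequency[!st$probe_id %in% planted] <
                    st$frequency[st$probe_id %in% planted][1] + 1))
  never <- st$probe_id[st$frequency == 0]
  expect_true(length(never) > 0)
  expect_true(all(st$low_stability[st$probe_id %in% never]))
})

test_that("permutation preserves the label multiset and destroys performance", {
  co <- small_cohort(n_probes = 245, seed = 141)
  X <- t(co$beta); y <- co$sheet$condition
  perm <- permutation_control(X, y, n_permutations = 2, seed = 51,
                              keepX_grid = 45, M = 3, repeats = 3)
  expect_length(perm, 2)
  for (p in perm) {
    expect_identical(sort(attr(p, "permuted_labels")), sort(y))
  }
  true_rep <- cross_validate(X, y, keepX_grid = 45, M = 3, repeats = 3, seed = 51)
  expect_gt(true_rep$metrics$auc - perm[[1]]$metrics$auc, 0.3)
})

test_that("cross-validated AUC sits at chance on zero-signal data and rises with delta-beta", {
  aucs <- vapply(c(0, 0.14), function(d) {
    spec <- synthetic_spec(n_probes = 245, n_per_class = c(EOPE = 21, nPTB = 21),
                           class_means = c(0.54 - d / 2, 0.54 + d / 2), seed = 97)
    co <- generate_cohort(spec)
    rep <- cross_validate(t(co$beta), co$sheet$condition, keepX_grid = 45,
                          M = 3, repeats = 5, seed = 61)
    rep$metrics$auc
  }, numeric(1))
  expect_lt(abs(aucs[1] - 0.5), 0.1)
  expect_gt(aucs[2], aucs[1] + 0.2)
})
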