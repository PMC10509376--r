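# Repeated stratified M-fold cross-validation, performance metrics,
# feature-stability analysis, permutation controls, and threshold selection.

#' Stratified fold assignments for repeated M-fold cross-validation
#'
#' Partitions the cohort into `M` folds within each repeat. With
#' `stratified = TRUE` (default) the partition is drawn within each class so
#' that per-class counts differ by at most one across folds — the sensible
#' behaviour for a small two-class cohort. One master seed drives a
#' deterministic per-repeat substream, so any repeat is individually
#' reproducible.
#'
#' @param labels Class labels, one per sample.
#' @param M Number of folds (default 3).
#' @param repeats Number of repeats (default 50).
#' @param seed Master seed (integer) for the fold stream.
#' @param stratified Stratify by class (default TRUE).
#' @return A tibble with columns `repeat_id`, `index` (sample position) and
#'   `fold`.
#' @export
stratified_folds <- function(labels, M = 3, repeats = 50, seed = NULL,
                             stratified = TRUE) {
  n <- length(labels)
  M <- as.integer(M)
  if (stratified) {
    cnt <- table(labels)
    if (any(cnt < M)) {
      abort_validation(sprintf("Class '%s' has fewer than M = %d members.",
                               names(cnt)[which.min(cnt)], M))
    }
  } else if (n < M) abort_validation("Fewer samples than folds.")
  seed <- seed %||% sample.int(2147483647, 1)
  repeat_seeds <- with_seed(seed, sample.int(2147483647, repeats))
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- integer(n)
    with_seed(repeat_seeds[r], {
      groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
      for (idx in groups) {
        # random permutation of 1:M repeated, so the fold(s) receiving the
        # extra samples vary across classes and repeats
        fold[sample(idx)] <- rep_len(sample.int(M), length(idx))
      }
    })
    out[[r]] <- tibble::tibble(repeat_id = r, index = seq_len(n), fold = fold)
  }
  dplyr::bind_rows(out)
}

#' Overall and per-class misclassification error rate
#'
#' Overall error rate (OER) is the number of incorrect predictions divided
#' by the total number of samples; per-class OER restricts both counts to
#' one true class.
#'
#' @param calls Predicted class labels.
#' @param truth True class labels.
#' @return A list: `overall` and `per_class` (named vector; `NA` for an
#'   empty class).
#' @export
compute_oer <- function(calls, truth) {
  if (length(calls) != length(truth)) abort_validation("calls/truth length mismatch.")
  wrong <- calls != truth
  per_class <- vapply(sort(unique(as.character(truth))), function(cl) {
    in_cl <- truth == cl
    if (!any(in_cl)) NA_real_ else mean(wrong[in_cl])
  }, numeric(1))
  list(overall = mean(wrong), per_class = per_class)
}

#' Rank-statistic AUC
#'
#' The probability that a randomly chosen positive sample receives a higher
#' positive-class probability than a randomly chosen negative sample, with
#' ties counted 1/2 (Mann-Whitney form).
#'
#' @param probabilities Positive-class probabilities (any monotone score
#'   works).
#' @param truth True class labels.
#' @param positive Label of the positive class.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(probabilities, truth, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort_validation("Both classes must be present to compute AUC.")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between the predicted probability and the binary
#' outcome. The default `"binary"` convention scores the positive class
#' only, `mean((p - y)^2)` with `y = 1` for the positive class; the
#' `"multiclass"` convention sums the squared error over both class
#' probabilities, which for two classes is exactly twice the binary value.
#' Reports should state which convention was used.
#'
#' @param probabilities Positive-class probabilities in \[0, 1\].
#' @param truth True class labels.
#' @param positive Label of the positive class.
#' @param convention `"binary"` (default) or `"multiclass"`.
#' @return The Brier score.
#' @export
compute_brier <- function(probabilities, truth, positive,
                          convention = c("binary", "multiclass")) {
  convention <- match.arg(convention)
  if (any(probabilities < 0 | probabilities > 1)) {
    abort_validation("Probabilities must be in [0, 1].")
  }
  y <- as.numeric(truth == positive)
  b <- mean((probabilities - y)^2)
  if (convention == "multiclass") 2 * b else b
}

#' Confusion-matrix metrics
#'
#' @param calls Predicted class labels.
#' @param truth True class labels.
#' @param positive Label of the positive class.
#' @return A list: `tp`, `fn`, `tn`, `fp`, `sensitivity` = TP/(TP+FN),
#'   `specificity` = TN/(TN+FP) (`NA` when a class is empty).
#' @export
confusion_metrics <- function(calls, truth, positive) {
  is_pos <- truth == positive
  called_pos <- calls == positive
  tp <- sum(is_pos & called_pos); fn <- sum(is_pos & !called_pos)
  tn <- sum(!is_pos & !called_pos); fp <- sum(!is_pos & called_pos)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

#' Youden's J threshold selection
#'
#' Sweeps candidate thresholds at the midpoints of adjacent sorted unique
#' probabilities (a sample is called positive iff its probability is at or
#' above the threshold) and returns the threshold maximizing
#' J = sensitivity + specificity - 1; ties go to the lowest threshold.
#'
#' @inheritParams compute_auc
#' @return A list: `threshold`, `j`, and `roc`, a tibble of class
#'   `roc_curve` (`threshold`, `sensitivity`, `specificity`, `j`) with the
#'   rank-statistic AUC as attribute `auc`.
#' @export
youden_threshold <- function(probabilities, truth, positive) {
  pos <- truth == positive
  if (!any(pos) || all(pos)) abort_validation("Both classes needed for threshold selection.")
  u <- sort(unique(probabilities))
  cand <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else u
  roc <- purrr::map_dfr(cand, function(t) {
    cm <- confusion_metrics(ifelse(probabilities >= t, "pos", "neg"),
                            ifelse(pos, "pos", "neg"), "pos")
    tibble::tibble(threshold = t, sensitivity = cm$sensitivity,
                   specificity = cm$specificity)
  })
  roc$j <- roc$sensitivity + roc$specificity - 1
  best <- which(roc$j >= max(roc$j) - 1e-12)[1]
  attr(roc, "auc") <- compute_auc(probabilities, truth, positive)
  attr(roc, "positive_class") <- positive
  class(roc) <- c("roc_curve", class(roc))
  list(threshold = roc$threshold[best], j = roc$j[best], roc = roc)
}

# Fit on the training rows and return held-out probabilities/calls for one
# split. Scaling, feature selection and fitting see ONLY the training rows.
fit_predict_split <- function(X, y, train, test, keepX, n_components,
                              class_labels) {
  model <- fit_splsda(X[train, , drop = FALSE], y[train],
                      n_components = n_components, keepX = keepX,
                      class_labels = class_labels)
  pred <- predict(model, X[test, , drop = FALSE])
  list(model = model, pred = pred, selected = selected_features(model))
}

#' Repeated cross-validation with a keepX model-size sweep
#'
#' For each repeat x fold and each candidate `keepX`, fits a sparse PLS-DA
#' model on the training folds only — feature scaling, feature selection
#' and fitting all happen inside the fold, so no information leaks from
#' held-out samples — and predicts the held-out fold. Metrics (OER,
#' per-class OER, AUC, Brier) are pooled over the held-out samples within a
#' repeat and then averaged across repeats; per-fold AUC averaging is
#' available via `auc_mode = "fold"`.
#'
#' @param X Samples x features matrix (QC'd, normalized, complete).
#' @param y Class labels, one per row of `X`.
#' @param keepX_grid Candidate per-component feature budgets
#'   (default `c(90, 75, 60, 45, 30, 15, 5)`).
#' @param n_components Number of latent components (default 1).
#' @param M Folds per repeat (default 3).
#' @param repeats Number of repeats (default 50).
#' @param seed Master seed for the fold stream.
#' @param class_labels Ordered pair fixing the positive class (first).
#' @param auc_mode `"pooled"` (default) or `"fold"`.
#' @param brier_convention Passed to [compute_brier()].
#' @param stratified Stratify folds by class (default TRUE).
#' @param folds Optional precomputed fold tibble (as returned by
#'   [stratified_folds()]); overrides `M`, `repeats`, `seed`.
#' @return An object of class `cv_report`: `config`, `predictions`
#'   (per repeat x fold x keepX held-out records), `selections` (per-fit
#'   selected features), `metrics` (per-keepX aggregate tibble mirroring a
#'   model-size sweep table: OER, OER SD, per-class OER, AUC, Brier),
#'   `stability` (per-feature selection frequencies).
#' @export
cross_validate <- function(X, y, keepX_grid = c(90, 75, 60, 45, 30, 15, 5),
                           n_components = 1, M = 3, repeats = 50, seed = NULL,
                           class_labels = NULL, auc_mode = c("pooled", "fold"),
                           brier_convention = c("binary", "multiclass"),
                           stratified = TRUE, folds = NULL) {
  auc_mode <- match.arg(auc_mode)
  brier_convention <- match.arg(brier_convention)
  y <- as.character(y)
  class_labels <- class_labels %||% sort(unique(y))
  positive <- class_labels[1]
  keepX_grid <- sort(unique(as.integer(keepX_grid)), decreasing = TRUE)
  if (any(keepX_grid > ncol(X))) {
    abort_validation("keepX_grid contains budgets larger than the feature count.")
  }
  if (is.null(folds)) {
    folds <- stratified_folds(y, M = M, repeats = repeats, seed = seed,
                              stratified = stratified)
  } else {
    repeats <- max(folds$repeat_id)
    M <- max(folds$fold)
  }
  sample_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))

  preds <- list()
  sels <- list()
  k <- 0L
  for (r in seq_len(repeats)) {
    fr <- folds[folds$repeat_id == r, ]
    for (f in seq_len(M)) {
      test <- fr$index[fr$fold == f]
      train <- fr$index[fr$fold != f]
      for (kx in keepX_grid) {
        res <- fit_predict_split(X, y, train, test, kx, n_components, class_labels)
        k <- k + 1L
        preds[[k]] <- tibble::tibble(
          repeat_id = r, fold = f, keepX = kx,
          sample_id = sample_ids[test],
          truth = y[test],
          prob_pos = res$pred[[paste0("prob_", positive)]],
          call_max = res$pred$class_max)
        sels[[k]] <- tibble::tibble(repeat_id = r, fold = f, keepX = kx,
                                    probe_id = res$selected)
      }
    }
  }
  predictions <- dplyr::bind_rows(preds)
  selections <- dplyr::bind_rows(sels)

  report <- structure(list(
    config = list(M = M, repeats = repeats, keepX_grid = keepX_grid,
                  n_components = n_components, seed = seed,
                  class_labels = class_labels, positive = positive,
                  auc_mode = auc_mode, brier_convention = brier_convention,
                  stratified = stratified),
    folds = folds,
    predictions = predictions,
    selections = selections
  ), class = "cv_report")
  report$metrics <- cv_metrics(report)
  report$stability <- dplyr::bind_rows(
    lapply(keepX_grid, function(kx) feature_stability(report, kx,
                                                      feature_ids = colnames(X))))
  report
}

# Aggregate per-keepX metrics from the stored per-fold records.
cv_metrics <- function(report) {
  cfg <- report$config
  positive <- cfg$positive
  per_repeat <- report$predictions |>
    dplyr::group_by(.data$keepX, .data$repeat_id) |>
    dplyr::summarise(
      oer = mean(.data$call_max != .data$truth),
      oer_pos = mean(.data$call_max[.data$truth == positive] != positive),
      oer_neg = mean(.data$call_max[.data$truth != positive] !=
                       .data$truth[.data$truth != positive]),
      auc = if (cfg$auc_mode == "pooled") {
        compute_auc(.data$prob_pos, .data$truth, positive)
      } else {
        mean(vapply(split(seq_along(.data$prob_pos), .data$fold), function(i) {
          compute_auc(.data$prob_pos[i], .data$truth[i], positive)
        }, numeric(1)))
      },
      brier = compute_brier(.data$prob_pos, .data$truth, positive,
                            cfg$brier_convention),
      .groups = "drop")
  per_repeat |>
    dplyr::group_by(.data$keepX) |>
    dplyr::summarise(
      oer_sd = stats::sd(.data$oer), oer = mean(.data$oer),
      oer_positive = mean(.data$oer_pos), oer_negative = mean(.data$oer_neg),
      auc_sd = stats::sd(.data$auc), auc = mean(.data$auc),
      brier_sd = stats::sd(.data$brier), brier = mean(.data$brier),
      .groups = "drop") |>
    dplyr::select("keepX", "oer", "oer_sd", "oer_positive", "oer_negative",
                  "auc", "auc_sd", "brier", "brier_sd") |>
    dplyr::arrange(dplyr::desc(.data$keepX))
}

#' Per-feature selection frequency (stability)
#'
#' The fraction of cross-validation fits (folds x repeats) in which a
#' feature received a nonzero loading; features below `low_cutoff`
#' (default 0.5) are labelled low-stability.
#'
#' @param report A `cv_report`.
#' @param keepX The model size to extract.
#' @param low_cutoff Stability cutoff (default 0.5).
#' @param feature_ids Optional full feature universe; features never
#'   selected then appear with frequency 0.
#' @return A tibble: `keepX`, `probe_id`, `frequency`, `low_stability`.
#' @export
feature_stability <- function(report, keepX, low_cutoff = 0.5,
                              feature_ids = NULL) {
  sel <- report$selections[report$selections$keepX == keepX, ]
  if (nrow(sel) == 0) abort_validation(sprintf("No selections recorded for keepX = %d.", keepX))
  n_fits <- report$config$M * report$config$repeats
  freq <- table(sel$probe_id) / n_fits
  out <- tibble::tibble(probe_id = names(freq), frequency = as.numeric(freq))
  if (!is.null(feature_ids)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      probe_id = setdiff(feature_ids, out$probe_id), frequency = 0))
    out <- out[match(intersect(feature_ids, out$probe_id), out$probe_id), ]
  }
  out$keepX <- as.integer(keepX)
  out$low_stability <- out$frequency < low_cutoff
  out[, c("keepX", "probe_id", "frequency", "low_stability")]
}

#' Permutation control for a cross-validated model
#'
#' Re-runs the full cross-validation after permuting the class labels
#' uniformly at random (seeded). On balanced data a permuted model should
#' perform at chance (OER and AUC near 0.5); comparing the permuted report
#' with the true-label report shows how much of the model's performance is
#' signal.
#'
#' @inheritParams cross_validate
#' @param n_permutations Number of independent label permutations (default 1).
#' @param ... Passed on to [cross_validate()].
#' @return A list of `cv_report` objects, one per permutation, each with the
#'   permuted labels attached as attribute `permuted_labels`.
#' @export
permutation_control <- function(X, y, n_permutations = 1, seed = NULL, ...) {
  seed <- seed %||% sample.int(2147483647, 1)
  lapply(seq_len(n_permutations), function(i) {
    perm_seed <- derive_seed(seed, i)
    y_perm <- with_seed(perm_seed, sample(as.character(y)))
    rep <- cross_validate(X, y_perm, seed = derive_seed(seed, i + n_permutations), ...)
    attr(rep, "permuted_labels") <- y_perm
    rep
  })
}

#' Per-group signature beta summary
#'
#' For a set of signature features, computes the mean beta per class over
#' all (sample, feature) values, the absolute group difference
#' (delta beta), and a Welch two-sample t-test on the per-sample signature
#' means.
#'
#' @param beta Probes x samples beta matrix.
#' @param labels Class labels aligned to the samples.
#' @param feature_set Probe ids of the signature (subset of rownames).
#' @return A list: `group_means` (named), `delta_beta`, `t_statistic`,
#'   `p_value`, `per_sample` (tibble `sample_id`, `condition`, `mean_beta`).
#' @export
signature_delta_beta <- function(beta, labels, feature_set) {
  beta <- validate_beta_matrix(beta)
  missing <- setdiff(feature_set, rownames(beta))
  if (length(missing) > 0) abort_data(sprintf("%d signature feature(s) absent from beta.",
                                              length(missing)))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2 || any(table(labels) == 0)) {
    abort_validation("signature_delta_beta needs two non-empty groups.")
  }
  sub <- beta[feature_set, , drop = FALSE]
  per_sample <- tibble::tibble(sample_id = colnames(sub),
                               condition = as.character(labels),
                               mean_beta = colMeans(sub))
  group_means <- vapply(classes, function(cl) mean(sub[, labels == cl]), numeric(1))
  tt <- stats::t.test(per_sample$mean_beta[per_sample$condition == classes[1]],
                      per_sample$mean_beta[per_sample$condition == classes[2]])
  list(group_means = group_means,
       delta_beta = abs(unname(diff(group_means))),
       t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       per_sample = per_sample)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold x %d repeats, ncomp = %d, positive class %s\n",
              x$config$M, x$config$repeats, x$config$n_components,
              x$config$positive))
  cat(sprintf("  AUC mode: %s; Brier convention: %s\n",
              x$config$auc_mode, x$config$brier_convention))
  print(x$metrics)
  invisible(x)
}
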