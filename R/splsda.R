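#' One-hot encode class labels
#'
#' Builds the samples x classes indicator ("dummy") matrix used as the
#' response block in PLS discriminant analysis.
#'
#' @param labels Character or factor vector of class labels.
#' @param class_labels Ordered vector of the allowed classes; fixes the
#'   dummy-column order. Defaults to `sort(unique(labels))`.
#' @return An integer indicator matrix with one column per class.
#' @export
one_hot <- function(labels, class_labels = NULL) {
  labels <- as.character(labels)
  class_labels <- class_labels %||% sort(unique(labels))
  unseen <- setdiff(unique(labels), class_labels)
  if (length(unseen) > 0) {
    abort_validation(paste0("Unseen label(s): ", paste(unseen, collapse = ", ")))
  }
  if (length(unique(labels)) < 2) {
    abort_validation("Both classes must be present to train a discriminant model.")
  }
  Y <- vapply(class_labels, function(cl) as.integer(labels == cl),
              integer(length(labels)))
  dimnames(Y) <- list(names(labels), class_labels)
  Y
}

#' Sparse feature selection by soft-thresholding
#'
#' Shrinks a weight vector so that (up to ties) exactly `keepX` entries stay
#' nonzero, then rescales to unit Euclidean norm. The threshold is the
#' `(keepX + 1)`-th largest absolute weight (`0` when `keepX` equals the
#' vector length):
#' `out_i = sign(w_i) * max(|w_i| - lambda, 0)`.
#'
#' Ties at the threshold are broken toward the lowest index: the keep-set is
#' chosen by a stable ordering on decreasing `|w|`, and in the fully
#' degenerate case where shrinkage would zero every kept entry (all kept
#' `|w|` equal the threshold), the kept entries retain their unshrunk values
#' before normalization so that the budget is honoured.
#'
#' @param w Numeric weight vector.
#' @param keepX Integer budget of nonzero entries, `1 <= keepX <= length(w)`.
#' @return A unit-norm vector with at most `keepX` nonzero entries.
#' @export
select_features <- function(w, keepX) {
  p <- length(w)
  if (length(keepX) != 1 || is.na(keepX) || keepX < 1 || keepX > p) {
    abort_validation(sprintf("`keepX` must be in [1, %d].", p))
  }
  keepX <- as.integer(keepX)
  aw <- abs(w)
  ord <- order(aw, seq_len(p), decreasing = c(TRUE, FALSE), method = "radix")
  keep <- ord[seq_len(keepX)]
  lambda <- if (keepX < p) aw[ord[keepX + 1L]] else 0
  out <- numeric(p)
  shrunk <- aw[keep] - lambda
  if (all(shrunk <= 0)) {
    # complete tie at the threshold: keep unshrunk values (lowest indices win)
    out[keep] <- w[keep]
  } else {
    out[keep] <- sign(w[keep]) * pmax(shrunk, 0)
  }
  nrm <- l2norm(out)
  if (nrm == 0) abort_numerical("Feature selection produced a zero loading vector.")
  out / nrm
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Trains a sparse PLS-DA model on a samples x features matrix of beta
#' values against a two-class outcome. Features and the one-hot response
#' are centred and scaled to unit variance. For each component the NIPALS
#' pair of weight vectors is iterated on the cross-product of the current
#' (deflated) blocks, with the X-side weight soft-thresholded to the
#' component's `keepX` budget (see [select_features()]); scores, regression
#' coefficients and deflation follow the standard PLS recursion:
#' `t_h = X_h u_h`, `c_h = X_h't_h / t_h't_h`, `d_h = Y_h't_h / t_h't_h`,
#' `X_{h+1} = X_h - t_h c_h'`, `Y_{h+1} = Y_h - t_h d_h'`.
#'
#' The component-1 loading sign is fixed so that the positive class (the
#' first of `class_labels`) has the higher mean component-1 score; this is
#' a pure reporting convention and does not change predictions.
#'
#' @param X Samples x features numeric matrix with feature column names.
#' @param y Class labels, one per row of `X`.
#' @param n_components Number of latent components `H` (default 1; one
#'   component is the usual choice for a two-class outcome).
#' @param keepX Integer vector of per-component feature budgets; a single
#'   value is recycled across components. Defaults to all features (dense
#'   PLS-DA).
#' @param tol Convergence tolerance on the change in the X-weight vector.
#' @param max_iter Maximum NIPALS iterations per component.
#' @param class_labels Ordered pair fixing the dummy-column order and the
#'   positive class (first element). Defaults to `sort(unique(y))`.
#' @param decision_threshold Probability threshold stored with the model
#'   for thresholded calls at prediction time (default 0.55).
#' @return An object of class `splsda_model`.
#' @seealso [predict.splsda_model()], [write_model()]
#' @export
fit_splsda <- function(X, y, n_components = 1, keepX = NULL,
                       tol = 1e-6, max_iter = 100, class_labels = NULL,
                       decision_threshold = 0.55) {
  if (!is.matrix(X) || !is.numeric(X)) abort_validation("`X` must be a numeric matrix.")
  if (is.null(colnames(X))) abort_validation("`X` must have feature column names.")
  if (anyNA(X)) abort_data("`X` contains missing values; impute or filter upstream.")
  if (nrow(X) != length(y)) abort_validation("`y` must have one label per row of `X`.")
  H <- as.integer(n_components)
  if (H < 1) abort_validation("`n_components` must be >= 1.")
  p <- ncol(X)
  keepX <- keepX %||% p
  keepX <- as.integer(rep_len(keepX, H))
  if (any(keepX < 1 | keepX > p)) abort_validation("`keepX` values must be in [1, ncol(X)].")

  Y <- one_hot(y, class_labels)
  class_labels <- colnames(Y)

  xs <- scale_stats(X)
  zero_var <- which(xs$sd == 0 | !is.finite(xs$sd))
  if (length(zero_var) > 0) {
    abort_data(sprintf("Zero-variance feature(s): %s. Filter them upstream.",
                       paste(colnames(X)[utils::head(zero_var, 5)], collapse = ", ")))
  }
  Ym <- Y
  storage.mode(Ym) <- "double"
  ys <- scale_stats(Ym)
  Xh <- apply_scaling(X, xs)
  Yh <- apply_scaling(Ym, ys)

  loadings <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  x_coefs <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  y_coefs <- matrix(0, length(class_labels), H, dimnames = list(class_labels, NULL))
  converged <- logical(H)

  for (h in seq_len(H)) {
    M <- crossprod(Xh, Yh)                      # p x q cross-product block
    v <- svd(M, nu = 0, nv = 1)$v[, 1]
    u <- numeric(p)
    for (it in seq_len(max_iter)) {
      u_new <- select_features(drop(M %*% v), keepX[h])
      v_raw <- drop(crossprod(M, u_new))
      v <- v_raw / l2norm(v_raw)
      if (max(abs(u_new - u)) < tol) {
        u <- u_new
        converged[h] <- TRUE
        break
      }
      u <- u_new
    }
    if (!converged[h]) {
      rlang::warn(sprintf("Component %d did not converge in %d iterations.", h, max_iter))
    }
    t_h <- drop(Xh %*% u)
    tt <- sum(t_h^2)
    if (tt < .Machine$double.eps) abort_numerical(sprintf("Component %d has zero score variance.", h))
    c_h <- drop(crossprod(Xh, t_h)) / tt
    d_h <- drop(crossprod(Yh, t_h)) / tt

    if (h == 1L) {
      pos <- y == class_labels[1]
      if (mean(t_h[pos]) < mean(t_h[!pos])) {
        u <- -u; t_h <- -t_h; c_h <- -c_h; d_h <- -d_h
      }
    }

    loadings[, h] <- u
    x_coefs[, h] <- c_h
    y_coefs[, h] <- d_h
    Xh <- Xh - tcrossprod(t_h, c_h)
    Yh <- Yh - tcrossprod(t_h, d_h)
  }

  structure(list(
    class_labels = class_labels,
    feature_ids = colnames(X),
    feature_means = xs$mean,
    feature_sds = xs$sd,
    y_means = ys$mean,
    y_sds = ys$sd,
    n_components = H,
    keepX = keepX,
    loadings = loadings,
    x_regression_coefs = x_coefs,
    y_regression_coefs = y_coefs,
    decision_threshold = decision_threshold,
    converged = converged,
    schema_version = "1.0"
  ), class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  nz <- colSums(x$loadings != 0)
  cat(sprintf("<splsda_model> %d component(s), classes %s (positive: %s)\n",
              x$n_components, paste(x$class_labels, collapse = " vs "),
              x$class_labels[1]))
  cat(sprintf("  features: %d total; selected per component: %s (keepX %s)\n",
              length(x$feature_ids), paste(nz, collapse = ", "),
              paste(x$keepX, collapse = ", ")))
  cat(sprintf("  decision threshold: %.2f\n", x$decision_threshold))
  invisible(x)
}

#' Features selected by a fitted model
#'
#' @param model An `splsda_model`.
#' @return Character vector of features with a nonzero loading on any
#'   component, in feature order.
#' @export
selected_features <- function(model) {
  stopifnot(inherits(model, "splsda_model"))
  model$feature_ids[rowSums(model$loadings != 0) > 0]
}

#' Predict class membership with a sparse PLS-DA model
#'
#' Scales new samples with the training statistics, computes component
#' scores through the stored loadings and deflation coefficients, and maps
#' the cumulative score contribution back to the dummy scale (predicted
#' dummy values per class, the "prediction distances"). Two decision rules
#' are reported: the maximum-distance rule (class with the largest predicted
#' dummy value, ties to the first class label) and a probability-threshold
#' rule, where class probabilities are the softmax of the per-sample dummy
#' scores and the positive class is called iff its probability meets
#' `threshold`.
#'
#' @param object A fitted `splsda_model`.
#' @param newdata Samples x features matrix containing at least the model's
#'   `feature_ids` as named columns; extra columns are ignored.
#' @param threshold Probability threshold for the thresholded call;
#'   defaults to the model's stored `decision_threshold`.
#' @param ... Unused.
#' @return A tibble of class `splsda_prediction` with one row per sample:
#'   `sample_id`, `score_<class>` (predicted dummy values), `prob_<class>`
#'   (softmax probabilities, rows sum to 1), `class_max` and
#'   `class_threshold`. Attributes record the threshold and positive class.
#' @export
predict.splsda_model <- function(object, newdata, threshold = NULL, ...) {
  threshold <- threshold %||% object$decision_threshold
  if (!is.matrix(newdata)) abort_validation("`newdata` must be a matrix (samples x features).")
  missing <- setdiff(object$feature_ids, colnames(newdata))
  if (length(missing) > 0) {
    abort_data(sprintf("newdata is missing %d model feature(s): %s%s",
                       length(missing),
                       paste(utils::head(missing, 5), collapse = ", "),
                       if (length(missing) > 5) ", ..." else ""))
  }
  X <- newdata[, object$feature_ids, drop = FALSE]
  if (anyNA(X)) abort_data("`newdata` contains missing values at model features.")
  Xh <- apply_scaling(X, list(mean = object$feature_means, sd = object$feature_sds))
  n <- nrow(Xh)
  q <- length(object$class_labels)
  S <- matrix(0, n, q)
  for (h in seq_len(object$n_components)) {
    t_h <- drop(Xh %*% object$loadings[, h])
    S <- S + tcrossprod(t_h, object$y_regression_coefs[, h])
    Xh <- Xh - tcrossprod(t_h, object$x_regression_coefs[, h])
  }
  dummy <- sweep(sweep(S, 2, object$y_sds, "*"), 2, object$y_means, "+")
  colnames(dummy) <- object$class_labels
  prob <- t(apply(dummy, 1, function(s) {
    e <- exp(s - max(s))                        # stabilised softmax
    e / sum(e)
  }))
  colnames(prob) <- object$class_labels
  class_max <- object$class_labels[max.col(dummy, ties.method = "first")]
  pos <- object$class_labels[1]
  class_thr <- ifelse(prob[, pos] >= threshold, pos, object$class_labels[2])
  sample_ids <- rownames(newdata) %||% as.character(seq_len(n))
  out <- tibble::tibble(sample_id = sample_ids)
  for (cl in object$class_labels) out[[paste0("score_", cl)]] <- dummy[, cl]
  for (cl in object$class_labels) out[[paste0("prob_", cl)]] <- prob[, cl]
  out$class_max <- class_max
  out$class_threshold <- class_thr
  attr(out, "threshold") <- threshold
  attr(out, "positive_class") <- pos
  attr(out, "class_labels") <- object$class_labels
  class(out) <- c("splsda_prediction", class(out))
  out
}
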