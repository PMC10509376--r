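# Beta-mixture quantile (BMIQ) and between-sample quantile normalization.
#
# Illumina arrays mix two probe chemistries: type II probes show a
# compressed beta distribution relative to type I. BMIQ fits a
# 3-component beta mixture (unmethylated U, hemimethylated H, methylated M)
# to each probe type within a sample and maps the type II distribution onto
# the type I scale by quantile matching of the U and M components and a
# linear dilation of the H component. Normalization is strictly per-sample;
# quantile normalization, in contrast, operates across the whole matrix.

clip_unit <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

#' Fit a 3-component beta mixture by EM
#'
#' Fits mixture weights and per-component beta shape parameters to a vector
#' of beta values. The E-step computes responsibilities from the current
#' parameters; the M-step updates each component's shapes by
#' method-of-moments from responsibility-weighted means and variances.
#' Components are labelled U/H/M by ascending mean. Initialization splits
#' the values at fixed thresholds (`init_breaks`, default 0.2 and 0.75).
#'
#' @param values Beta values in (0, 1); values at the boundary are clipped
#'   by 1e-6 (the beta density is unbounded there). >= 100 values
#'   recommended.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-4).
#' @param max_iter Maximum EM iterations (default 100).
#' @param init_breaks Two cutpoints splitting values into initial U/H/M
#'   groups.
#' @return An object of class `beta_mixture_fit`: `weights`, `shape_a`,
#'   `shape_b`, `means`, `component_order` (`U`, `H`, `M`), `loglik`
#'   (per-iteration trace), `converged`, `n_iter`.
#' @export
fit_beta_mixture <- function(values, tol = 1e-4, max_iter = 100,
                             init_breaks = c(0.2, 0.75)) {
  x <- clip_unit(values[!is.na(values)])
  n <- length(x)
  if (n < 10) abort_validation("Need at least 10 values to fit a beta mixture.")
  grp <- findInterval(x, init_breaks) + 1L
  # guard: every initial group needs a few members
  for (k in 1:3) if (sum(grp == k) < 3) {
    qs <- stats::quantile(x, c(1, 2) / 3, names = FALSE)
    grp <- findInterval(x, qs) + 1L
    break
  }
  mom <- function(m, v) {
    v <- max(min(v, m * (1 - m) * 0.999), 1e-8)
    phi <- m * (1 - m) / v - 1
    c(a = max(m * phi, 1e-3), b = max((1 - m) * phi, 1e-3))
  }
  w <- tabulate(grp, 3) / n
  ab <- t(vapply(1:3, function(k) {
    xi <- x[grp == k]
    if (length(xi) < 2) xi <- x
    mom(mean(xi), stats::var(xi))
  }, numeric(2)))

  ll_trace <- numeric(0)
  converged <- FALSE
  dens <- matrix(0, n, 3)
  for (it in seq_len(max_iter)) {
    for (k in 1:3) dens[, k] <- w[k] * stats::dbeta(x, ab[k, 1], ab[k, 2])
    rs <- rowSums(dens)
    rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(rs))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol * abs(ll_trace[it - 1])) {
      converged <- TRUE
      break
    }
    r <- dens / rs
    wk <- colSums(r)
    w <- wk / n
    if (any(w < 1e-3)) {
      abort_numerical("Beta-mixture component collapsed (weight < 1e-3); fit fewer states.")
    }
    for (k in 1:3) {
      m <- sum(r[, k] * x) / wk[k]
      v <- sum(r[, k] * (x - m)^2) / wk[k]
      ab[k, ] <- mom(m, v)
    }
  }
  means <- ab[, 1] / rowSums(ab)
  ord <- order(means)
  structure(list(
    n_components = 3L,
    weights = w[ord],
    shape_a = ab[ord, 1],
    shape_b = ab[ord, 2],
    means = means[ord],
    component_order = c("U", "H", "M"),
    loglik = ll_trace,
    converged = converged,
    n_iter = length(ll_trace)
  ), class = "beta_mixture_fit")
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat("<beta_mixture_fit> components (U/H/M):\n")
  print(tibble::tibble(state = x$component_order, weight = x$weights,
                       mean = x$means, shape_a = x$shape_a, shape_b = x$shape_b))
  cat(sprintf("  converged: %s after %d iterations\n", x$converged, x$n_iter))
  invisible(x)
}

mixture_posterior <- function(x, fit) {
  d <- vapply(1:3, function(k) {
    fit$weights[k] * stats::dbeta(x, fit$shape_a[k], fit$shape_b[k])
  }, numeric(length(x)))
  d <- matrix(d, ncol = 3)
  d / rowSums(d)
}

#' BMIQ-normalize one sample
#'
#' Maps the type II beta distribution of a single sample onto its type I
#' scale. Type I probes pass through unchanged. Each type II probe is
#' assigned to the U, H or M state by maximum posterior under the type II
#' mixture fit (ties broken toward the lower-mean state); U-state probes
#' are mapped by `p = CDF_U2(beta)`, `beta' = CDF_U1^{-1}(p)`, M-state
#' probes symmetrically through the `1 - beta` reflection of the M
#' components, and H-state probes by a linear dilation anchoring the H
#' interval between the maximum of the transformed U values and the minimum
#' of the transformed M values. Output is clipped to \[0, 1\]; the mapping
#' is monotone non-decreasing within each state.
#'
#' @param sample_betas Named (or not) vector of betas for one sample.
#' @param design_type Character vector (`"I"`/`"II"`), one entry per probe.
#' @param tol,max_iter,init_breaks Passed to [fit_beta_mixture()].
#' @return A list: `betas` (adjusted vector, same order), `fit_type1`,
#'   `fit_type2` (the two mixture fits), `state` (assigned state per type II
#'   probe).
#' @export
bmiq_normalize <- function(sample_betas, design_type,
                           tol = 1e-4, max_iter = 100, init_breaks = c(0.2, 0.75)) {
  if (length(sample_betas) != length(design_type)) {
    abort_validation("`design_type` must have one entry per probe.")
  }
  is2 <- design_type == "II"
  if (!any(is2) || all(is2)) {
    abort_validation("BMIQ needs both type I and type II probes in the sample.")
  }
  b1 <- sample_betas[!is2]
  b2 <- sample_betas[is2]
  fit1 <- fit_beta_mixture(b1, tol, max_iter, init_breaks)
  fit2 <- fit_beta_mixture(b2, tol, max_iter, init_breaks)

  x2 <- clip_unit(b2)
  post <- mixture_posterior(x2, fit2)
  # max posterior; ties toward the lower-mean state (states ordered U<H<M)
  state <- apply(post, 1, function(p) which(p >= max(p) - 1e-12)[1])

  out2 <- numeric(length(x2))
  uU <- state == 1L; uH <- state == 2L; uM <- state == 3L
  if (any(uU)) {
    p <- stats::pbeta(x2[uU], fit2$shape_a[1], fit2$shape_b[1])
    out2[uU] <- stats::qbeta(p, fit1$shape_a[1], fit1$shape_b[1])
  }
  if (any(uM)) {
    p <- stats::pbeta(1 - x2[uM], fit2$shape_b[3], fit2$shape_a[3])
    out2[uM] <- 1 - stats::qbeta(p, fit1$shape_b[3], fit1$shape_a[3])
  }
  if (any(uH)) {
    h <- x2[uH]
    lo2 <- min(h); hi2 <- max(h)
    if (any(uU)) lo1 <- max(out2[uU]) else {
      rlang::warn("No U-state type II probes; H dilation anchored at the H minimum.")
      lo1 <- lo2
    }
    if (any(uM)) hi1 <- min(out2[uM]) else {
      rlang::warn("No M-state type II probes; H dilation anchored at the H maximum.")
      hi1 <- hi2
    }
    if (hi2 > lo2 && hi1 > lo1) {
      out2[uH] <- lo1 + (h - lo2) * (hi1 - lo1) / (hi2 - lo2)
    } else {
      rlang::warn("Degenerate H interval; H-state probes left unchanged.")
      out2[uH] <- h
    }
  }
  adjusted <- sample_betas
  adjusted[is2] <- pmin(pmax(out2, 0), 1)
  list(betas = adjusted, fit_type1 = fit1, fit_type2 = fit2, state = state)
}

#' Normalize a beta matrix
#'
#' Matrix-level front-end over the two implemented methods. `"bmiq"`
#' normalizes each sample independently (no information crosses samples);
#' `"quantile"` is the classical between-sample method and uses the whole
#' matrix. The distinction is explicit in the interface because per-sample
#' vs between-sample normalization changes what leaks between samples.
#'
#' @param beta Probes x samples beta matrix.
#' @param annotation Probe annotation with `probe_id` and `design_type`
#'   (required for BMIQ).
#' @param method `"bmiq"` or `"quantile"`.
#' @param ... Passed to [bmiq_normalize()].
#' @return A list: `beta` (normalized matrix) and `log` (per-sample mixture
#'   fit summaries for BMIQ; empty for quantile).
#' @export
normalize_betas <- function(beta, annotation = NULL,
                            method = c("bmiq", "quantile"), ...) {
  method <- match.arg(method)
  beta <- validate_beta_matrix(beta)
  if (method == "quantile") {
    return(list(beta = quantile_normalize(beta), log = list()))
  }
  if (is.null(annotation) || !"design_type" %in% names(annotation)) {
    abort_validation("BMIQ requires an annotation with `design_type`.")
  }
  dt <- annotation$design_type[match(rownames(beta), annotation$probe_id)]
  if (anyNA(dt)) abort_data("Annotation does not cover all probes (design_type).")
  out <- beta
  log <- vector("list", ncol(beta))
  names(log) <- colnames(beta)
  for (j in seq_len(ncol(beta))) {
    res <- bmiq_normalize(beta[, j], dt, ...)
    out[, j] <- res$betas
    log[[j]] <- list(
      type2_means = res$fit_type2$means,
      type2_weights = res$fit_type2$weights,
      converged = res$fit_type2$converged && res$fit_type1$converged)
  }
  list(beta = out, log = log)
}

#' Between-sample quantile normalization
#'
#' Replaces each sample's sorted values by the across-sample mean of order
#' statistics; after normalization every column has an identical sorted
#' vector. Ties within a column receive the mean of the reference values at
#' their would-be positions (average ranks interpolate between adjacent
#' order-statistic means).
#'
#' @param beta Probes x samples beta matrix (complete).
#' @return The quantile-normalized matrix.
#' @export
quantile_normalize <- function(beta) {
  beta <- validate_beta_matrix(beta)
  if (anyNA(beta)) abort_data("quantile_normalize requires a complete matrix.")
  sorted <- apply(beta, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(beta, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(beta)
  out
}
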