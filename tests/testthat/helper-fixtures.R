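# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

make_beta <- function(nr, nc, values = NULL, seed = 42) {
  vals <- values %||% withr::with_seed(seed, stats::runif(nr * nc, 0.05, 0.95))
  matrix(vals, nr, nc,
         dimnames = list(sprintf("cg%05d", seq_len(nr)),
                         sprintf("S%02d", seq_len(nc))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Re-apply a model's training scaling to a matrix (for score checks).
apply_scaling_for_test <- function(X, m) {
  sweep(sweep(X[, m$feature_ids, drop = FALSE], 2, m$feature_means, "-"),
        2, m$feature_sds, "/")
}

# A small two-class cohort with a planted signature, cheap enough for
# repeated CV inside tests.
small_cohort <- function(n_probes = 545, n_signature = 45, seed = 11, ...) {
  spec <- synthetic_spec(n_probes = n_probes, n_signature = n_signature,
                         seed = seed, ...)
  generate_cohort(spec)
}

# Reference-scale cohort (the generator defaults) and its CV run, computed
# once per test session and shared by the end-to-end checks.
acceptance_env <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(acceptance_env$cohort)) {
    acceptance_env$cohort <- generate_cohort(synthetic_spec(seed = 1))
  }
  acceptance_env$cohort
}

acceptance_cv <- function() {
  if (is.null(acceptance_env$cv)) {
    co <- acceptance_cohort()
    acceptance_env$cv <- cross_validate(t(co$beta), co$sheet$condition,
                                        keepX_grid = 45, n_components = 1,
                                        M = 3, repeats = 50, seed = 2024)
  }
  acceptance_env$cv
}
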