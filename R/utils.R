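# Internal helpers shared across modules.

# Run `code` under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483587 + 1)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "methylpls_validation_error", ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "methylpls_data_error", ...)
}

abort_numerical <- function(msg, ...) {
  rlang::abort(msg, class = "methylpls_numerical_error", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

l2norm <- function(x) sqrt(sum(x^2))

# Column-wise centering/scaling that keeps the statistics for later reuse.
scale_stats <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  list(mean = mu, sd = sd)
}

apply_scaling <- function(X, stats) {
  sweep(sweep(X, 2, stats$mean, "-"), 2, stats$sd, "/")
}
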