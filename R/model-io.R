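MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a fitted sparse PLS-DA model to JSON
#'
#' The model is written as a single JSON document with a `schema_version`
#' field. Sparse loadings are stored as (index, value) pairs so that a
#' 45-of-341,281 signature stays compact; all numbers are written at full
#' precision so the round-trip is lossless.
#'
#' @param model A fitted `splsda_model` (must have >= 1 component).
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "splsda_model")) abort_validation("`model` must be an splsda_model.")
  if (is.null(model$n_components) || model$n_components < 1) {
    abort_validation("Model must have at least one component.")
  }
  if (any(!is.finite(model$feature_means)) || any(!is.finite(model$feature_sds)) ||
      any(model$feature_sds <= 0)) {
    abort_validation("Model scaling statistics must be finite with positive sds.")
  }
  sparse_loadings <- lapply(seq_len(model$n_components), function(h) {
    nz <- which(model$loadings[, h] != 0)
    list(index = nz, value = unname(model$loadings[nz, h]))
  })
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    class_labels = model$class_labels,
    feature_ids = model$feature_ids,
    feature_means = unname(model$feature_means),
    feature_sds = unname(model$feature_sds),
    y_means = unname(model$y_means),
    y_sds = unname(model$y_sds),
    n_components = model$n_components,
    keepX = model$keepX,
    loadings = sparse_loadings,
    x_regression_coefs = lapply(seq_len(model$n_components),
                                function(h) unname(model$x_regression_coefs[, h])),
    y_regression_coefs = lapply(seq_len(model$n_components),
                                function(h) unname(model$y_regression_coefs[, h])),
    decision_threshold = model$decision_threshold,
    converged = model$converged
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized sparse PLS-DA model
#'
#' @param path Path to a JSON file written by [write_model()].
#' @return An `splsda_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(doc$schema_version) || !identical(doc$schema_version, MODEL_SCHEMA_VERSION)) {
    abort_data(sprintf("Model schema version mismatch: file has %s, expected %s.",
                       doc$schema_version %||% "<none>", MODEL_SCHEMA_VERSION))
  }
  p <- length(doc$feature_ids)
  H <- as.integer(doc$n_components)
  q <- length(doc$class_labels)
  loadings <- matrix(0, p, H, dimnames = list(doc$feature_ids, NULL))
  for (h in seq_len(H)) {
    entry <- doc$loadings[[h]]
    loadings[unlist(entry$index), h] <- unlist(entry$value)
  }
  as_coef_matrix <- function(x, nr) matrix(unlist(x), nrow = nr, ncol = H)
  x_coefs <- as_coef_matrix(doc$x_regression_coefs, p)
  y_coefs <- as_coef_matrix(doc$y_regression_coefs, q)
  rownames(x_coefs) <- doc$feature_ids
  rownames(y_coefs) <- doc$class_labels
  model <- structure(list(
    class_labels = doc$class_labels,
    feature_ids = doc$feature_ids,
    feature_means = stats::setNames(doc$feature_means, doc$feature_ids),
    feature_sds = stats::setNames(doc$feature_sds, doc$feature_ids),
    y_means = stats::setNames(doc$y_means, doc$class_labels),
    y_sds = stats::setNames(doc$y_sds, doc$class_labels),
    n_components = H,
    keepX = as.integer(doc$keepX),
    loadings = loadings,
    x_regression_coefs = x_coefs,
    y_regression_coefs = y_coefs,
    decision_threshold = doc$decision_threshold,
    converged = as.logical(doc$converged),
    schema_version = doc$schema_version
  ), class = "splsda_model")
  model
}
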