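# broom-style tidiers for fitted models and CV reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted sparse PLS-DA model
#'
#' @param x An `splsda_model`.
#' @param ... Unused.
#' @return A tibble with one row per nonzero loading: `component`,
#'   `probe_id`, `loading`.
#' @method tidy splsda_model
#' @export
tidy.splsda_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_components), function(h) {
    nz <- which(x$loadings[, h] != 0)
    tibble::tibble(component = h,
                   probe_id = x$feature_ids[nz],
                   loading = unname(x$loadings[nz, h]))
  })
}

#' One-row model summary
#'
#' @param x An `splsda_model`.
#' @param ... Unused.
#' @return A tibble: `n_components`, `n_features`, `n_selected`,
#'   `positive_class`, `decision_threshold`, `converged`.
#' @method glance splsda_model
#' @export
glance.splsda_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_features = length(x$feature_ids),
                 n_selected = length(selected_features(x)),
                 positive_class = x$class_labels[1],
                 decision_threshold = x$decision_threshold,
                 converged = all(x$converged))
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The per-keepX aggregate metric tibble.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$metrics

#' One-row cross-validation summary (the smallest adequate model)
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A one-row tibble for the smallest keepX whose mean OER lies
#'   within one standard deviation of the best model's.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  m <- x$metrics
  m[m$keepX == knee_keepX(m), , drop = FALSE]
}
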