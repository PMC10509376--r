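# End-to-end pipeline orchestration: simulate -> qc -> [normalize] ->
# crossval -> train -> threshold -> predict, with every artifact written to
# a run directory so a run is auditable and resumable.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) abort_validation("`config` must be a list or a YAML/JSON path.")
  known <- c("seed", "stages", "synthetic", "qc", "normalize", "crossval",
             "train", "predict")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort_validation(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  config
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    abort_data(sprintf("Stage '%s' needs missing input artifact: %s", stage, path))
  }
  path
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the configured stages in order, each stage reading only
#' prior-stage artifacts from `out_dir` and writing its own. The fully
#' resolved configuration and a manifest (stage order, seeds, wall times,
#' record counts in/out) are written next to the outputs. Re-running with
#' the same config and seed reproduces all numeric outputs.
#'
#' Config keys (all optional; defaults in parentheses):
#' `seed` (1); `stages` (all); `synthetic` (arguments to
#' [synthetic_spec()]); `qc` (config list for [run_qc()]); `normalize`
#' (`method`: `"none"`, `"bmiq"` or `"quantile"`; default `"none"` — the
#' generator emits betas on a common scale unless type II compression is
#' being studied); `crossval` (`keepX_grid`, `n_components`, `M`,
#' `repeats`); `train` (`keepX`, `n_components`); `predict`
#' (`threshold` (0.55), `n_per_class`, `cohort_shift`).
#'
#' @param config A named list, or a path to a YAML/JSON file.
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with the main in-memory results: `qc`,
#'   `cv_report`, `model`, `threshold`, `predictions`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  stages <- config$stages %||% c("simulate", "qc", "normalize", "crossval",
                                 "train", "threshold", "predict")
  manifest <- list(seed = seed, stages = list())
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    manifest$stages[[name]] <<- c(list(
      wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      attr(res, "counts") %||% list())
    res
  }
  with_counts <- function(...) { x <- list(); attr(x, "counts") <- list(...); x }
  paths <- list(
    beta = file.path(out_dir, "beta.tsv"),
    sheet = file.path(out_dir, "sample_sheet.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    truth = file.path(out_dir, "truth.json"),
    qc_beta = file.path(out_dir, "beta_qc.tsv"),
    qc_sheet = file.path(out_dir, "sample_sheet_qc.tsv"),
    qc_report = file.path(out_dir, "qc_report.tsv"),
    norm_beta = file.path(out_dir, "beta_norm.tsv"),
    cv_metrics = file.path(out_dir, "cv_metrics.tsv"),
    stability = file.path(out_dir, "stability.tsv"),
    model = file.path(out_dir, "model.json"),
    roc = file.path(out_dir, "roc_points.tsv"),
    threshold = file.path(out_dir, "threshold.json"),
    predictions = file.path(out_dir, "predictions.tsv"))

  out <- list()
  spec <- do.call(synthetic_spec,
                  utils::modifyList(list(seed = seed), config$synthetic %||% list()))

  if ("simulate" %in% stages) {
    t_stage("simulate", {
      cohort <- generate_cohort(spec)
      write_beta_matrix(cohort$beta, paths$beta)
      readr::write_tsv(cohort$sheet, paths$sheet, progress = FALSE)
      readr::write_tsv(cohort$annotation, paths$annotation, progress = FALSE)
      jsonlite::write_json(cohort$truth[c("signature_probes", "contaminated_samples",
                                          "sex_discordant_samples", "bad_probes")],
                           paths$truth, auto_unbox = TRUE, digits = NA)
      saveRDS(cohort$qc, file.path(out_dir, "qc_matrices.rds"))
      with_counts(probes = nrow(cohort$beta), samples = ncol(cohort$beta))
    })
  }

  if ("qc" %in% stages) {
    t_stage("qc", {
      beta <- read_beta_matrix(require_artifact(paths$beta, "qc"))
      sheet <- read_sample_sheet(require_artifact(paths$sheet, "qc"))
      annotation <- read_probe_annotation(require_artifact(paths$annotation, "qc"))
      qcm <- readRDS(require_artifact(file.path(out_dir, "qc_matrices.rds"), "qc"))
      res <- run_qc(beta, sheet, qcm, annotation, config$qc %||% list())
      write_beta_matrix(res$beta, paths$qc_beta)
      readr::write_tsv(res$sheet, paths$qc_sheet, progress = FALSE)
      write_qc_report(res$report, paths$qc_report)
      out$qc <- res
      with_counts(probes_in = nrow(beta), probes_out = nrow(res$beta),
                  samples_in = ncol(beta), samples_out = ncol(res$beta))
    })
  }

  norm_method <- (config$normalize %||% list())$method %||% "none"
  if ("normalize" %in% stages && norm_method != "none") {
    t_stage("normalize", {
      beta <- read_beta_matrix(require_artifact(paths$qc_beta, "normalize"))
      annotation <- read_probe_annotation(require_artifact(paths$annotation, "normalize"))
      res <- normalize_betas(beta, annotation, method = norm_method)
      write_beta_matrix(res$beta, paths$norm_beta)
      NULL
    })
  } else if ("normalize" %in% stages) {
    file.copy(require_artifact(paths$qc_beta, "normalize"), paths$norm_beta,
              overwrite = TRUE)
  }

  load_training <- function(stage) {
    beta <- read_beta_matrix(require_artifact(paths$norm_beta, stage))
    sheet <- read_sample_sheet(require_artifact(paths$qc_sheet, stage))
    list(X = t(beta), y = sheet$condition)
  }

  if ("crossval" %in% stages) {
    t_stage("crossval", {
      tr <- load_training("crossval")
      cvc <- config$crossval %||% list()
      report <- cross_validate(
        tr$X, tr$y,
        keepX_grid = cvc$keepX_grid %||% c(90, 75, 60, 45, 30, 15, 5),
        n_components = cvc$n_components %||% 1,
        M = cvc$M %||% 3, repeats = cvc$repeats %||% 50,
        seed = derive_seed(seed, 11))
      metrics <- report$metrics
      # the model-size decision is annotated, not automated: flag the knee
      metrics$knee <- metrics$keepX == knee_keepX(metrics)
      readr::write_tsv(metrics, paths$cv_metrics, progress = FALSE)
      readr::write_tsv(report$stability, paths$stability, progress = FALSE)
      out$cv_report <- report
      with_counts(fits = nrow(report$selections))
    })
  }

  if ("train" %in% stages) {
    t_stage("train", {
      tr <- load_training("train")
      tc <- config$train %||% list()
      model <- fit_splsda(tr$X, tr$y,
                          n_components = tc$n_components %||% 1,
                          keepX = tc$keepX %||% 45)
      write_model(model, paths$model)
      out$model <- model
      with_counts(features_selected = length(selected_features(model)))
    })
  }

  if ("threshold" %in% stages) {
    t_stage("threshold", {
      model <- read_model(require_artifact(paths$model, "threshold"))
      tr <- load_training("threshold")
      pred <- predict(model, tr$X)
      pos <- model$class_labels[1]
      yt <- youden_threshold(pred[[paste0("prob_", pos)]], tr$y, pos)
      readr::write_tsv(yt$roc, paths$roc, progress = FALSE)
      jsonlite::write_json(list(threshold = yt$threshold, youden_j = yt$j,
                                positive_class = pos, rule = "prob >= threshold"),
                           paths$threshold, auto_unbox = TRUE, digits = NA)
      out$threshold <- yt
      NULL
    })
  }

  if ("predict" %in% stages) {
    t_stage("predict", {
      model <- read_model(require_artifact(paths$model, "predict"))
      pc <- config$predict %||% list()
      val <- generate_validation_cohort(
        spec, model_feature_ids = model$feature_ids,
        n_per_class = pc$n_per_class,
        cohort_shift = pc$cohort_shift %||% 0,
        seed = derive_seed(seed, 21))
      pred <- predict(model, t(val$beta), threshold = pc$threshold %||% 0.55)
      pred$truth <- val$sheet$condition
      hdr <- sprintf("# threshold = %s (positive class %s); scores are predicted dummy values; probabilities are softmax over scores",
                     format(attr(pred, "threshold")), attr(pred, "positive_class"))
      writeLines(hdr, paths$predictions)
      readr::write_tsv(pred, paths$predictions, append = TRUE,
                       col_names = TRUE, progress = FALSE)
      out$predictions <- pred
      with_counts(samples = nrow(pred))
    })
  }

  jsonlite::write_json(config, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

# Smallest keepX whose OER is within one OER SD of the best model: the
# "knee" of the model-size sweep, reported as an annotation for the user.
knee_keepX <- function(metrics) {
  best <- min(metrics$oer)
  tol <- metrics$oer_sd[which.min(metrics$oer)]
  min(metrics$keepX[metrics$oer <= best + tol])
}
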