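#' Configuration for the full three-layer pipeline
#'
#' Bundles the stage configurations: train/test split, optional rejection
#' layer, selection layer (fast + accurate stage) and the diagnostic
#' classifier. One global seed deterministically derives every stage seed.
#'
#' @param rl_enabled run GA outlier rejection on the training partition.
#' @param rl an [or_config()] for the rejection layer.
#' @param sl_enabled run the selection layer.
#' @param method selection method passed to [select_features()].
#' @param fs_v fast-stage survivor count or fraction.
#' @param hoa an [hoa_config()] for the accurate stage.
#' @param classifier "nb" or "knn".
#' @param nb_alpha Laplace smoothing for NB.
#' @param knn_k neighbourhood size for KNN.
#' @param train_fraction training proportion of the stratified split.
#' @param seed global integer seed.
#' @param output_dir optional directory; when set, [run_pipeline()] writes
#'   the selected features, removed rows and metrics there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(rl_enabled = FALSE, rl = or_config(),
                            sl_enabled = TRUE, method = "hfsa",
                            fs_v = 0.5, hoa = hoa_config(),
                            classifier = c("nb", "knn"), nb_alpha = 1,
                            knn_k = 7, train_fraction = 0.7, seed = 1,
                            output_dir = NULL) {
  classifier <- match.arg(classifier)
  structure(list(rl_enabled = isTRUE(rl_enabled), rl = rl,
                 sl_enabled = isTRUE(sl_enabled), method = method,
                 fs_v = fs_v, hoa = hoa, classifier = classifier,
                 nb_alpha = nb_alpha, knn_k = knn_k,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the three-layer diagnostic pipeline
#'
#' Executes: stratified split, GA outlier rejection on the training
#' partition only (if enabled), chi-square fast stage plus hybrid wrapper
#' accurate stage (if enabled), classifier fit on the filtered training
#' data, and evaluation on the untouched test partition. Test rows are
#' never seen by any training stage. Byte-identical reruns under the same
#' config and seed.
#'
#' @param config a [pipeline_config()].
#' @param ds a `symptom_dataset`.
#' @return a `pipeline_report` list: `metrics` (accuracy/error/precision/
#'   recall and, for NB, auc — all percentages), `selected_features`,
#'   `removed_indices` (into the training partition), `selection`
#'   (the `selection_result`, or NULL), `confusion`, `stage_seeds`, `log`
#'   (one line per stage) and `config`.
#' @export
run_pipeline <- function(config, ds) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(ds, "symptom_dataset"))
  seeds <- list(split = derive_seed(config$seed, "split"),
                rl = derive_seed(config$seed, "rl"),
                sl = derive_seed(config$seed, "sl"))
  log_lines <- character(0)
  log_stage <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("[%s] %s", name, conditionMessage(e))
    })
  }

  sp <- step("split",
             stratified_split(ds, config$train_fraction, seeds$split))
  train <- sp$train
  test <- sp$test
  log_stage("split: %d train / %d test (seed %d)",
            n_cases(train), n_cases(test), seeds$split)

  removed <- integer(0)
  if (config$rl_enabled) {
    rlc <- config$rl
    rlc$seed <- seeds$rl
    rej <- step("rejection_layer", reject_outliers(train, rlc))
    train <- rej$dataset
    removed <- rej$removed_indices
    log_stage("rejection_layer: removed %d of %d rows, fitness %.4f",
              length(removed), n_cases(sp$train), rej$best_fitness)
  }

  selection <- NULL
  if (config$sl_enabled) {
    slc <- config$hoa
    slc$seed <- seeds$sl
    selection <- step("selection_layer",
                      select_features(train, config$method, config$fs_v, slc))
    fmask <- integer(n_features(ds))
    fmask[selection$kept_original_indices] <- 1L
    train <- apply_mask(train, fmask)
    test <- apply_mask(test, fmask)
    log_stage("selection_layer: %s kept %d features, best fitness %.4f",
              config$method, selection$m, selection$best_fitness)
  }

  if (config$classifier == "nb") {
    model <- step("diagnostic_layer", nb_fit(train, config$nb_alpha))
    post <- nb_predict_proba(model, test)
    pred <- nb_predict(model, test)
    colnames(post) <- model$classes
    auc <- suppressWarnings(roc_auc_macro(test$labels, post))
  } else {
    pred <- step("diagnostic_layer", knn_predict(train, test, config$knn_k))
    auc <- NA_real_
  }
  classes <- sort(unique(ds$labels))
  cm <- confusion(test$labels, pred, classes)
  metrics <- c(cm_metrics(cm), auc = auc)
  log_stage("diagnostic_layer: %s accuracy %.2f%%",
            config$classifier, metrics[["accuracy"]])

  report <- structure(list(metrics = metrics,
                           selected_features = if (is.null(selection)) ds$feature_names
                                               else selection$selected_features,
                           removed_indices = removed,
                           selection = selection,
                           confusion = cm,
                           stage_seeds = seeds,
                           log = log_lines,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(config$output_dir)) write_pipeline_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("three-layer diagnostic pipeline report\n")
  for (l in x$log) cat(" ", l, "\n")
  m <- x$metrics
  cat(sprintf("  test metrics: accuracy %.2f%%, error %.2f%%, precision %.2f%%, recall %.2f%%%s\n",
              m[["accuracy"]], m[["error"]], m[["precision"]], m[["recall"]],
              if (!is.na(m[["auc"]])) sprintf(", auc %.2f%%", m[["auc"]]) else ""))
  invisible(x)
}

write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report$selected_features, file.path(dir, "selected_features.txt"))
  writeLines(as.character(report$removed_indices),
             file.path(dir, "removed_indices.txt"))
  utils::write.csv(data.frame(metric = names(report$metrics),
                              value = unname(report$metrics)),
                   file.path(dir, "metrics.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(report$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' Read a key/value configuration file
#'
#' Minimal YAML-like format: one `key: value` pair per line, `#` comments
#' allowed; values are parsed as logical, numeric, or string.
#'
#' @param path path to the config file.
#' @return named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", l))[[1]]
    if (length(m) != 3) stopf("unparseable config line: '%s'", l)
    key <- m[2]; val <- trimws(m[3])
    out[[key]] <- if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
  }
  out
}
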