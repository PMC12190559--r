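#' Confusion matrix
#'
#' @param true_labels vector of true labels.
#' @param predicted_labels vector of predicted labels, same length.
#' @param classes ordered class list; defaults to the sorted union of both
#'   label vectors.
#' @return integer matrix (rows = true, columns = predicted) with class
#'   dimnames.
#' @export
confusion <- function(true_labels, predicted_labels, classes = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stopf("label vectors differ in length")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(true_labels),
                             as.character(predicted_labels))))
  } else if (!all(c(true_labels, predicted_labels) %in% classes)) {
    stopf("label absent from the supplied class list")
  }
  t_f <- factor(true_labels, levels = classes)
  p_f <- factor(predicted_labels, levels = classes)
  cm <- table(t_f, p_f)
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Confusion-matrix summary metrics
#'
#' Accuracy is `100 * trace / total` and error is its complement, so
#' `accuracy + error == 100` exactly. Precision and recall are
#' macro-averaged over classes (diagonal over column sum, diagonal over row
#' sum); a class with an empty denominator contributes 0. All values are
#' percentages.
#'
#' @param cm confusion matrix from [confusion()].
#' @return named numeric vector: `accuracy`, `error`, `precision`, `recall`.
#' @export
cm_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  acc <- 100 * sum(diag(cm)) / total
  col_s <- colSums(cm)
  row_s <- rowSums(cm)
  prec <- ifelse(col_s > 0, diag(cm) / col_s, 0)
  rec <- ifelse(row_s > 0, diag(cm) / row_s, 0)
  c(accuracy = acc, error = 100 - acc,
    precision = 100 * mean(prec), recall = 100 * mean(rec))
}

#' Macro one-vs-rest ROC-AUC
#'
#' Per class, the AUC is the Mann-Whitney rank statistic of the class's
#' posterior column (ties contribute 1/2); classes with zero positives or
#' zero negatives are skipped with a warning. The macro average is returned
#' as a percentage.
#'
#' @param true_labels vector of true labels.
#' @param posterior matrix of class posteriors with columns named (or
#'   ordered) by `classes`.
#' @param classes class order of the posterior columns; defaults to the
#'   matrix's column names.
#' @return macro AUC in [0, 100].
#' @export
roc_auc_macro <- function(true_labels, posterior, classes = colnames(posterior)) {
  if (is.null(classes)) stopf("supply classes or name the posterior columns")
  if (length(true_labels) != nrow(posterior)) {
    stopf("posterior rows != number of labels")
  }
  aucs <- numeric(0)
  for (j in seq_along(classes)) {
    pos <- true_labels == classes[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      warnf("class '%s' has no positives or no negatives; skipped", classes[j])
      next
    }
    r <- rank(posterior[, j])
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  if (length(aucs) == 0) stopf("no class with both positives and negatives")
  100 * mean(aucs)
}

#' k-nearest-neighbour baseline classifier
#'
#' Hamming-distance KNN with majority vote. Distance ties are broken by the
#' lower training-row index and vote ties by class (sorted) order. The
#' default `k = 7` follows the study's tuning.
#'
#' @param train,test `symptom_dataset`s with equal feature counts.
#' @param k neighbourhood size, `1 <= k <= n_cases(train)`.
#' @return character vector of predicted labels for `test`.
#' @export
knn_predict <- function(train, test, k = 7) {
  stopifnot(inherits(train, "symptom_dataset"),
            inherits(test, "symptom_dataset"))
  if (n_features(train) != n_features(test)) stopf("feature count mismatch")
  if (k < 1 || k > n_cases(train)) {
    stopf("k must lie in 1..%d", n_cases(train))
  }
  classes <- sort(unique(train$labels))
  xt <- train$cases
  xs <- test$cases
  # Hamming distance via two inner products (both matrices are 0/1)
  d <- n_features(train) - xs %*% t(xt) - (1 - xs) %*% t(1 - xt)
  out <- character(nrow(xs))
  for (i in seq_len(nrow(xs))) {
    nn <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
    votes <- table(factor(train$labels[nn], levels = classes))
    out[i] <- classes[which.max(votes)]
  }
  out
}

#' Stratified k-fold cross-validation of a diagnostic pipeline
#'
#' Splits the dataset into `k` stratified folds (default 10) and, per fold,
#' runs the configured pipeline on the training folds only — optional GA
#' outlier rejection, optional feature selection, then the classifier — and
#' evaluates on the held-out fold. The `Average` row is the arithmetic mean
#' of the per-fold metrics.
#'
#' @param ds a `symptom_dataset`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment and stage seeds.
#' @param classifier "nb" or "knn".
#' @param nb_alpha Laplace smoothing for the NB classifier.
#' @param knn_k neighbourhood size for the KNN classifier.
#' @param rl optional [or_config()] enabling outlier rejection per fold.
#' @param selection optional list(`method`, `v`, `config`) enabling the
#'   selection layer per fold (see [select_features()]).
#' @return list of class `cv_report`: `per_fold` data frame (fold,
#'   accuracy, error, precision, recall, and auc for NB), `average` named
#'   vector, and `folds` (the fold assignment).
#' @export
kfold_cv <- function(ds, k = 10, seed = 1, classifier = c("nb", "knn"),
                     nb_alpha = 1, knn_k = 7, rl = NULL, selection = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(ds, "symptom_dataset"))
  if (k < 2 || k > n_cases(ds)) stopf("k must lie in 2..%d", n_cases(ds))
  folds <- stratified_folds(ds$labels, k, derive_seed(seed, "cv_folds"))
  classes <- sort(unique(ds$labels))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te_idx <- which(folds == f)
    tr <- remove_rows(ds, te_idx)
    te <- remove_rows(ds, setdiff(seq_len(n_cases(ds)), te_idx))
    if (!is.null(rl)) {
      rlc <- rl
      rlc$seed <- derive_seed(seed, paste0("rl_fold", f))
      tr <- reject_outliers(tr, rlc)$dataset
    }
    if (!is.null(selection)) {
      slc <- selection$config %||% hoa_config()
      slc$seed <- derive_seed(seed, paste0("sl_fold", f))
      sel <- select_features(tr, selection$method %||% "hfsa",
                             selection$v %||% 0.5, slc)
      fmask <- integer(n_features(ds))
      fmask[sel$kept_original_indices] <- 1L
      tr <- apply_mask(tr, fmask)
      te <- apply_mask(te, fmask)
    }
    if (classifier == "nb") {
      model <- nb_fit(tr, nb_alpha)
      post <- nb_predict_proba(model, te)
      pred <- nb_predict(model, te)
      colnames(post) <- model$classes
      auc <- suppressWarnings(roc_auc_macro(te$labels, post))
    } else {
      pred <- knn_predict(tr, te, knn_k)
      auc <- NA_real_
    }
    met <- cm_metrics(confusion(te$labels, pred, classes))
    rows[[f]] <- c(fold = f, met, auc = auc)
  }
  per_fold <- as.data.frame(do.call(rbind, rows))
  average <- colMeans(per_fold[, -1, drop = FALSE])
  structure(list(per_fold = per_fold, average = average, folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  df <- x$per_fold
  df$fold <- as.character(df$fold)
  avg <- c(fold = "Average", vapply(x$average, function(z)
    sprintf("%.2f", z), character(1)))
  for (col in names(df)[-1]) df[[col]] <- sprintf("%.2f", df[[col]])
  print(rbind(df, avg), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Five-number summary across independent runs
#'
#' Summarises a list of per-run metric vectors with the inclusive
#' (median-of-halves) quartile convention, the convention used for run-level
#' boxplots.
#'
#' @param run_metrics list of named numeric vectors (one per run) or a
#'   numeric matrix with runs in rows.
#' @return data frame with one row per metric: min, q1, median, q3, max.
#' @export
multirun_summary <- function(run_metrics) {
  if (is.list(run_metrics)) {
    if (length(run_metrics) == 0) stopf("no runs supplied")
    run_metrics <- do.call(rbind, run_metrics)
  }
  if (is.null(dim(run_metrics))) run_metrics <- matrix(run_metrics, ncol = 1)
  five <- function(x) {
    x <- sort(x)
    n <- length(x)
    med <- stats::median(x)
    if (n <= 1) return(c(min = x[1], q1 = x[1], median = med,
                         q3 = x[1], max = x[n]))
    # inclusive convention: odd n keeps the median point in both halves
    lower <- x[seq_len(ceiling(n / 2))]
    upper <- x[seq(floor(n / 2) + 1, n)]
    c(min = x[1], q1 = stats::median(lower), median = med,
      q3 = stats::median(upper), max = x[n])
  }
  out <- t(apply(run_metrics, 2, five))
  data.frame(metric = colnames(run_metrics) %||% paste0("m", seq_len(nrow(out))),
             out, row.names = NULL)
}
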