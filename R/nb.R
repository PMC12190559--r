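#' Fit a Bernoulli naive-Bayes diagnostic model
#'
#' Class priors are empirical class frequencies; the per-class, per-feature
#' conditional probability of a symptom being present is Laplace-smoothed:
#' `(count of 1s in class + alpha) / (n_class + 2 * alpha)`.
#'
#' @param train a `symptom_dataset` with at least 2 classes and 1 feature.
#' @param alpha additive (Laplace) smoothing pseudo-count; default 1.
#' @return an `nb_model` with `class_priors`, `conditionals`
#'   (classes x features matrix), `classes` (sorted label order used for
#'   tie-breaks) and `feature_count`.
#' @export
nb_fit <- function(train, alpha = 1) {
  stopifnot(inherits(train, "symptom_dataset"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2) stopf("need at least 2 classes to fit")
  if (n_features(train) < 1) stopf("need at least 1 feature to fit")
  if (alpha < 0) stopf("alpha must be >= 0")
  y <- factor(train$labels, levels = classes)
  ind <- stats::model.matrix(~ y - 1)          # n x K one-hot
  n_c <- colSums(ind)
  ones <- crossprod(ind, train$cases)          # K x F counts of 1s
  cond <- (ones + alpha) / (n_c + 2 * alpha)
  structure(list(class_priors = as.numeric(n_c / sum(n_c)),
                 conditionals = unname(cond),
                 classes = classes,
                 feature_count = n_features(train),
                 alpha = alpha),
            class = "nb_model")
}

#' Posterior class probabilities under a naive-Bayes model
#'
#' Likelihoods are accumulated in log space and normalised per row with the
#' log-sum-exp trick; each returned row sums to 1.
#'
#' @param model an `nb_model`.
#' @param ds a `symptom_dataset` with the model's feature count.
#' @return numeric matrix, `n_cases(ds)` x number of classes; columns follow
#'   `model$classes`.
#' @export
nb_predict_proba <- function(model, ds) {
  logpost <- nb_logposterior(model, ds)
  mx <- apply(logpost, 1, max)
  p <- exp(logpost - mx)
  p / rowSums(p)
}

# shared log-posterior kernel: x . (l1 - l0) + sum(l0) + log prior per class.
# Both the predictor and the wrapper fitness use this exact formulation so
# exact posterior ties resolve identically everywhere.
nb_logposterior <- function(model, ds) {
  stopifnot(inherits(model, "nb_model"), inherits(ds, "symptom_dataset"))
  if (n_features(ds) != model$feature_count) {
    stopf("feature count mismatch: data has %d, model expects %d",
          n_features(ds), model$feature_count)
  }
  theta <- model$conditionals
  # alpha = 0 can produce exact 0/1 conditionals; clamp for log space
  eps <- 1e-300
  l1 <- log(pmax(theta, eps))
  l0 <- log(pmax(1 - theta, eps))
  base <- rowSums(l0) + log(pmax(model$class_priors, eps))
  lp <- ds$cases %*% t(l1 - l0)
  sweep(lp, 2, base, "+")
}

#' Predict disease labels
#'
#' Argmax of the log-posterior per case; ties go to the first class in
#' `model$classes`.
#'
#' @inheritParams nb_predict_proba
#' @return character vector of predicted labels.
#' @export
nb_predict <- function(model, ds) {
  lp <- nb_logposterior(model, ds)
  model$classes[max.col(lp, ties.method = "first")]
}

#' Deterministic stratified fold assignment
#'
#' @param labels label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      rows <- rows[sample.int(length(rows))]
      folds[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  folds
}

#' Build a cached naive-Bayes fitness function over feature masks
#'
#' Returns a closure mapping a 0/1 feature mask to the stratified
#' `eval_folds`-fold cross-validated naive-Bayes accuracy of the subset on
#' `train` — the wrapper objective of the accurate stage. Fold assignment is
#' fixed once from `seed`, so the fitness landscape is deterministic, and
#' results are memoised by the mask's bit string so duplicate masks are never
#' refit. The empty mask scores 0.
#'
#' @param train a `symptom_dataset`.
#' @param eval_folds number of internal CV folds (default 3).
#' @param seed integer seed for the fold assignment.
#' @param alpha Laplace smoothing for the embedded classifier.
#' @return function(mask) -> fitness in [0, 1].
#' @export
nb_fitness_fn <- function(train, eval_folds = 3, seed = 1, alpha = 1) {
  stopifnot(inherits(train, "symptom_dataset"))
  folds <- stratified_folds(train$labels, eval_folds, seed)
  classes <- sort(unique(train$labels))
  y <- factor(train$labels, levels = classes)
  x <- train$cases
  n <- nrow(x)
  eps <- 1e-300
  # per-fold sufficient statistics; the mask only subsets columns later,
  # so the wrapper loop never refits from raw rows
  fold_stats <- lapply(seq_len(eval_folds), function(f) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(te) == 0 || length(unique(train$labels[tr])) < 2) return(NULL)
    ind <- stats::model.matrix(~ y[tr] - 1)
    n_c <- colSums(ind)
    list(ones = crossprod(ind, x[tr, , drop = FALSE]),   # K x u counts of 1s
         n_c = n_c,
         log_prior = log(pmax(n_c / sum(n_c), eps)),
         xte = x[te, , drop = FALSE],
         yte = train$labels[te])
  })
  cache <- new.env(parent = emptyenv())
  function(mask) {
    mask <- as.integer(mask)
    if (length(mask) != ncol(x)) {
      stopf("mask length (%d) != feature count (%d)", length(mask), ncol(x))
    }
    if (sum(mask) == 0) return(0)
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    keep <- which(mask == 1L)
    correct <- 0L
    for (fs in fold_stats) {
      if (is.null(fs)) next
      theta <- (fs$ones[, keep, drop = FALSE] + alpha) / (fs$n_c + 2 * alpha)
      l1 <- log(pmax(theta, eps))
      l0 <- log(pmax(1 - theta, eps))
      # log-posterior = x . (l1 - l0) + sum(l0) + log prior, per class
      base <- rowSums(l0) + fs$log_prior
      lp <- fs$xte[, keep, drop = FALSE] %*% t(l1 - l0)
      lp <- sweep(lp, 2, base, "+")
      pred <- classes[max.col(lp, ties.method = "first")]
      correct <- correct + sum(pred == fs$yte)
    }
    val <- correct / n
    cache[[key]] <- val
    val
  }
}

#' Cross-validated naive-Bayes accuracy of a feature subset
#'
#' One-shot convenience wrapper around [nb_fitness_fn()]; identical masks,
#' data and seed always give identical fitness.
#'
#' @param mask 0/1 feature mask.
#' @param train a `symptom_dataset`.
#' @param eval_folds number of internal CV folds.
#' @param seed integer seed for the fold assignment.
#' @return fitness in [0, 1]; 0 for the empty mask.
#' @export
fitness_accuracy <- function(mask, train, eval_folds = 3, seed = 1) {
  nb_fitness_fn(train, eval_folds, seed)(mask)
}
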