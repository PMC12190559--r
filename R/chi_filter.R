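#' Chi-square association scores for every symptom
#'
#' For each feature, builds the 2 x n_classes contingency table of feature
#' value against disease label and returns the Pearson statistic
#' sum((O - E)^2 / E) over cells with positive expected count. A feature
#' constant across all cases has every expected count zero on one side and
#' scores exactly 0. Scores are a ranking device only; no p-values are
#' computed.
#'
#' @param ds a `symptom_dataset` with at least 2 classes.
#' @return numeric vector of non-negative scores, one per feature.
#' @export
chi_square_scores <- function(ds) {
  stopifnot(inherits(ds, "symptom_dataset"))
  classes <- sort(unique(ds$labels))
  if (length(classes) < 2) stopf("need at least 2 classes")
  y <- factor(ds$labels, levels = classes)
  ind <- stats::model.matrix(~ y - 1)         # n x K
  n_c <- colSums(ind)                         # class sizes
  n <- n_cases(ds)
  o1 <- crossprod(ind, ds$cases)              # K x F observed 1s
  p1 <- colSums(ds$cases) / n                 # feature-wise P(X = 1)
  e1 <- outer(n_c, p1)                        # K x F expected 1s
  e0 <- outer(n_c, 1 - p1)
  o0 <- sweep(-o1, 1, n_c, "+")
  chi <- function(o, e) {
    z <- (o - e)^2 / e
    z[e <= 0] <- 0
    z
  }
  as.numeric(colSums(chi(o1, e1)) + colSums(chi(o0, e0)))
}

#' Fast stage: keep the top-v features by chi-square score
#'
#' Ranks features by descending score (ties broken toward the lower column
#' index) and keeps the best `v`, a strict reduction of the feature space
#' before the wrapper stage. Survivors keep their original column order.
#'
#' @param ds a `symptom_dataset` with `u` features.
#' @param v number of features to keep (integer, `1 <= v < u`), or a
#'   fraction in (0, 1) converted as `ceiling(v * u)`. Default keeps
#'   `ceiling(u / 2)`.
#' @return list with `dataset` (reduced `symptom_dataset`), `scores`
#'   (all `u` scores) and `kept_indices` (original column indices of the
#'   survivors, in original order).
#' @export
run_fast_stage <- function(ds, v = 0.5) {
  stopifnot(inherits(ds, "symptom_dataset"))
  u <- n_features(ds)
  if (v > 0 && v < 1) v <- ceiling(v * u)
  v <- as.integer(v)
  if (v < 1 || v >= u) {
    stopf("v must satisfy 1 <= v < u = %d (got %d)", u, v)
  }
  scores <- chi_square_scores(ds)
  ranking <- order(-scores, seq_along(scores))
  kept <- sort(ranking[seq_len(v)])
  mask <- integer(u)
  mask[kept] <- 1L
  list(dataset = apply_mask(ds, mask),
       scores = scores,
       kept_indices = kept)
}
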