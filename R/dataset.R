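#' Construct a symptom dataset
#'
#' The core container of the package: a binary case-by-symptom matrix with one
#' disease label per case. Every cell must be exactly 0 or 1; a "1" means the
#' symptom is present in (affects) that case.
#'
#' @param cases integer/numeric matrix of 0/1, cases in rows, symptoms in
#'   columns.
#' @param labels vector of disease identifiers, one per row; coerced to
#'   character.
#' @param feature_names character vector of column names; defaults to the
#'   matrix's column names.
#' @return an object of class `symptom_dataset` with elements `cases`
#'   (integer matrix), `labels` (character) and `feature_names` (character).
#' @export
symptom_dataset <- function(cases, labels,
                            feature_names = colnames(cases)) {
  if (!is.matrix(cases)) cases <- as.matrix(cases)
  if (is.null(feature_names)) {
    feature_names <- paste0("symptom_", seq_len(ncol(cases)))
  }
  labels <- as.character(labels)
  bad <- which(!(cases == 0 | cases == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("non-binary cell at row %d, column '%s': value %s",
          bad[1, 1], feature_names[bad[1, 2]],
          format(cases[bad[1, 1], bad[1, 2]]))
  }
  if (length(labels) != nrow(cases)) {
    stopf("labels length (%d) != number of rows (%d)",
          length(labels), nrow(cases))
  }
  if (length(feature_names) != ncol(cases)) {
    stopf("feature_names length (%d) != number of columns (%d)",
          length(feature_names), ncol(cases))
  }
  storage.mode(cases) <- "integer"
  dimnames(cases) <- NULL
  structure(list(cases = cases, labels = labels,
                 feature_names = as.character(feature_names)),
            class = "symptom_dataset")
}

#' @export
print.symptom_dataset <- function(x, ...) {
  cat(sprintf("symptom_dataset: %d cases x %d symptoms, %d diseases\n",
              nrow(x$cases), ncol(x$cases), length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.symptom_dataset <- function(x) dim(x$cases)

#' Number of cases / features in a dataset
#' @param ds a `symptom_dataset`.
#' @return integer count.
#' @export
n_cases <- function(ds) nrow(ds$cases)

#' @rdname n_cases
#' @export
n_features <- function(ds) ncol(ds$cases)

#' Construct a feature mask
#'
#' A binary vector over the current feature set; a 1 marks a selected feature.
#'
#' @param bits vector of 0/1.
#' @return integer vector of class `feature_mask`.
#' @export
feature_mask <- function(bits) {
  bits <- as.integer(bits)
  if (any(is.na(bits)) || any(bits != 0L & bits != 1L)) {
    stopf("feature mask bits must all be 0 or 1")
  }
  structure(bits, class = "feature_mask")
}

#' Number of selected features in a mask
#' @param mask a `feature_mask` (or plain 0/1 vector).
#' @return integer popcount.
#' @export
mask_popcount <- function(mask) sum(as.integer(mask))

#' Read a symptom dataset from CSV
#'
#' The file must have a header row, one label column, and all remaining
#' columns strictly 0/1. Row and column order are preserved.
#'
#' @param path path to a delimited text file.
#' @param label_column name of the label column (default "prognosis").
#' @return a `symptom_dataset`.
#' @export
load_dataset <- function(path, label_column = "prognosis") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0 || ncol(df) == 0) stopf("empty file: %s", path)
  if (!label_column %in% names(df)) {
    stopf("label column '%s' not found in %s", label_column, path)
  }
  labels <- df[[label_column]]
  feats <- df[, names(df) != label_column, drop = FALSE]
  if (ncol(feats) == 0) stopf("no symptom columns in %s", path)
  mat <- matrix(NA_integer_, nrow(feats), ncol(feats))
  for (j in seq_len(ncol(feats))) {
    v <- feats[[j]]
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stopf("non-binary cell at row %d, column '%s': value '%s'",
            i, names(feats)[j], v[i])
    }
    mat[, j] <- as.integer(v)
  }
  symptom_dataset(mat, labels, names(feats))
}

#' Write a symptom dataset to CSV
#'
#' Writes a header of feature names plus the label column;
#' [load_dataset()] inverts it bit-exactly.
#'
#' @param ds a `symptom_dataset`.
#' @param path output file path.
#' @param label_column name for the label column (default "prognosis").
#' @return invisibly, `path`.
#' @export
save_dataset <- function(ds, path, label_column = "prognosis") {
  stopifnot(inherits(ds, "symptom_dataset"))
  if (n_features(ds) == 0) stopf("refusing to write a dataset with 0 features")
  df <- as.data.frame(ds$cases)
  names(df) <- ds$feature_names
  df[[label_column]] <- ds$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits by label so per-disease proportions are preserved to within
#' rounding. The training size is `round(n * train_fraction)`; at the
#' conventional 70/30 split of 4,920 cases this yields 3,444 / 1,476. Falls
#' back to a plain random split, with a warning, when any label has fewer
#' than 2 cases.
#'
#' @param ds a `symptom_dataset`.
#' @param train_fraction proportion of cases for training, in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with elements `train`, `test` (both `symptom_dataset`) and
#'   `train_indices`, `test_indices` (row indices into `ds`).
#' @export
stratified_split <- function(ds, train_fraction = 0.7, seed = 1) {
  stopifnot(inherits(ds, "symptom_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must lie strictly between 0 and 1")
  }
  n <- n_cases(ds)
  target <- round(n * train_fraction)
  counts <- table(ds$labels)
  train_idx <- with_seed(seed, {
    if (any(counts < 2)) {
      warnf("label(s) with fewer than 2 cases; falling back to a plain split")
      sample.int(n, target)
    } else {
      per_class <- split(seq_len(n), ds$labels)
      base <- floor(counts * train_fraction)
      remainder <- target - sum(base)
      frac <- counts * train_fraction - base
      # hand leftover slots to the classes with the largest fractional parts
      extra_order <- order(-frac, names(counts))
      take <- base
      if (remainder > 0) {
        sel <- extra_order[seq_len(remainder)]
        take[sel] <- take[sel] + 1
      } else if (remainder < 0) {
        sel <- rev(extra_order)[seq_len(-remainder)]
        take[sel] <- take[sel] - 1
      }
      idx <- unlist(lapply(names(per_class), function(cl) {
        rows <- per_class[[cl]]
        sample(rows, take[[cl]])
      }), use.names = FALSE)
      sort(idx)
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = remove_rows(ds, test_idx),
       test = remove_rows(ds, train_idx),
       train_indices = sort(train_idx),
       test_indices = sort(test_idx))
}

#' Restrict a dataset to the features selected by a mask
#'
#' @param ds a `symptom_dataset`.
#' @param mask 0/1 vector of length `n_features(ds)` with at least one 1.
#' @return a `symptom_dataset` holding exactly the selected columns, in
#'   original order.
#' @export
apply_mask <- function(ds, mask) {
  stopifnot(inherits(ds, "symptom_dataset"))
  mask <- as.integer(mask)
  if (length(mask) != n_features(ds)) {
    stopf("mask length (%d) != feature count (%d)",
          length(mask), n_features(ds))
  }
  if (sum(mask) == 0) stopf("invalid mask: empty feature subset")
  keep <- which(mask == 1L)
  symptom_dataset(ds$cases[, keep, drop = FALSE], ds$labels,
                  ds$feature_names[keep])
}

#' Remove rows from a dataset
#'
#' @param ds a `symptom_dataset`.
#' @param indices integer row indices to drop (1-based); may be empty.
#' @return a `symptom_dataset` with the surviving rows in original order.
#' @export
remove_rows <- function(ds, indices) {
  stopifnot(inherits(ds, "symptom_dataset"))
  indices <- unique(as.integer(indices))
  if (length(indices) == 0) return(ds)
  if (any(indices < 1 | indices > n_cases(ds))) {
    stopf("row index out of range 1..%d", n_cases(ds))
  }
  if (length(indices) == n_cases(ds)) stopf("cannot remove all rows")
  keep <- setdiff(seq_len(n_cases(ds)), indices)
  symptom_dataset(ds$cases[keep, , drop = FALSE], ds$labels[keep],
                  ds$feature_names)
}
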