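#' Configuration for the synthetic symptom-disease generator
#'
#' Defaults emulate the dimensions of the benchmark symptom-disease table
#' used throughout the package: 41 diseases, 132 symptoms, 120 cases per
#' disease (4,920 cases in all). Each disease owns a disjoint set of
#' characteristic symptoms which switch on with probability `p_on` in its
#' cases; every other symptom is background noise firing at `p_noise`.
#'
#' @param n_diseases number of disease classes.
#' @param n_features total number of symptom columns.
#' @param informative_per_disease characteristic symptoms per disease;
#'   `n_diseases * informative_per_disease` must not exceed `n_features`.
#' @param p_on probability a characteristic symptom is present in a case of
#'   its disease.
#' @param p_noise probability any non-characteristic symptom is present;
#'   must be strictly less than `p_on`.
#' @param cases_per_disease cases generated per disease.
#' @param outlier_fraction proportion of rows to corrupt, in [0, 0.5).
#' @param outlier_mode "label_shuffle" (reassign the label) or
#'   "symptom_scramble" (resample the row's bits Bernoulli(0.5)).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_diseases = 41, n_features = 132,
                             informative_per_disease = 3,
                             p_on = 0.9, p_noise = 0.05,
                             cases_per_disease = 120,
                             outlier_fraction = 0,
                             outlier_mode = c("label_shuffle",
                                              "symptom_scramble"),
                             seed = 1) {
  outlier_mode <- match.arg(outlier_mode)
  cfg <- list(n_diseases = as.integer(n_diseases),
              n_features = as.integer(n_features),
              informative_per_disease = as.integer(informative_per_disease),
              p_on = p_on, p_noise = p_noise,
              cases_per_disease = as.integer(cases_per_disease),
              outlier_fraction = outlier_fraction,
              outlier_mode = outlier_mode, seed = as.integer(seed))
  if (cfg$n_diseases * cfg$informative_per_disease > cfg$n_features) {
    stopf("infeasible config: %d diseases x %d informative symptoms > %d features",
          cfg$n_diseases, cfg$informative_per_disease, cfg$n_features)
  }
  if (!(cfg$p_noise >= 0 && cfg$p_noise < cfg$p_on && cfg$p_on <= 1)) {
    stopf("require 0 <= p_noise < p_on <= 1")
  }
  if (!(cfg$outlier_fraction >= 0 && cfg$outlier_fraction < 0.5)) {
    stopf("outlier_fraction must lie in [0, 0.5)")
  }
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a synthetic symptom-disease dataset with known ground truth
#'
#' Each disease receives a disjoint block of `informative_per_disease`
#' characteristic symptoms (assigned in column order), so the union of
#' characteristic symptoms is an unambiguous ground-truth informative mask
#' for feature-recovery experiments. Optionally corrupts a fraction of rows
#' via [inject_outliers()].
#'
#' @param config a [generator_config()].
#' @return list with `dataset` (a `symptom_dataset`) and `truth`, a list
#'   holding `informative_mask` (0/1 over columns), `outlier_indices`
#'   (corrupted row indices) and `disease_features` (per-disease
#'   characteristic column indices).
#' @export
generate_symptom_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  k <- config$n_diseases
  u <- config$n_features
  m <- config$informative_per_disease
  npc <- config$cases_per_disease
  n <- k * npc
  diseases <- sprintf("disease_%02d", seq_len(k))
  disease_features <- lapply(seq_len(k), function(d) ((d - 1) * m + 1):(d * m))
  mat <- with_seed(config$seed, {
    x <- matrix(as.integer(stats::runif(n * u) < config$p_noise), n, u)
    for (d in seq_len(k)) {
      rows <- ((d - 1) * npc + 1):(d * npc)
      cols <- disease_features[[d]]
      x[rows, cols] <- as.integer(
        stats::runif(length(rows) * length(cols)) < config$p_on)
    }
    x
  })
  labels <- rep(diseases, each = npc)
  ds <- symptom_dataset(mat, labels, sprintf("symptom_%03d", seq_len(u)))
  outliers <- integer(0)
  if (config$outlier_fraction > 0) {
    inj <- inject_outliers(ds, config$outlier_fraction, config$outlier_mode,
                           derive_seed(config$seed, "outliers"))
    ds <- inj$dataset
    outliers <- inj$outlier_indices
  }
  informative <- integer(u)
  informative[unlist(disease_features)] <- 1L
  list(dataset = ds,
       truth = list(informative_mask = feature_mask(informative),
                    outlier_indices = outliers,
                    disease_features = disease_features))
}

#' Plant outliers in a dataset
#'
#' Chooses `round(fraction * n)` rows without replacement and corrupts them:
#' `label_shuffle` reassigns each chosen row's label to a different,
#' uniformly random disease (symptom bits untouched); `symptom_scramble`
#' resamples the row's bits i.i.d. Bernoulli(0.5) (label untouched).
#'
#' @param ds a `symptom_dataset`.
#' @param fraction proportion of rows to corrupt, in [0, 0.5).
#' @param mode "label_shuffle" or "symptom_scramble".
#' @param seed integer seed.
#' @return list with `dataset` (corrupted copy) and `outlier_indices`
#'   (sorted corrupted row indices).
#' @export
inject_outliers <- function(ds, fraction,
                            mode = c("label_shuffle", "symptom_scramble"),
                            seed = 1) {
  stopifnot(inherits(ds, "symptom_dataset"))
  mode <- match.arg(mode)
  if (!(fraction >= 0 && fraction < 0.5)) {
    stopf("fraction must lie in [0, 0.5)")
  }
  n <- n_cases(ds)
  n_out <- round(fraction * n)
  if (n_out == 0) return(list(dataset = ds, outlier_indices = integer(0)))
  with_seed(seed, {
    idx <- sort(sample.int(n, n_out))
    if (mode == "label_shuffle") {
      classes <- unique(ds$labels)
      if (length(classes) < 2) stopf("label_shuffle needs >= 2 classes")
      for (i in idx) {
        others <- setdiff(classes, ds$labels[i])
        ds$labels[i] <- others[sample.int(length(others), 1)]
      }
    } else {
      ds$cases[idx, ] <- matrix(
        as.integer(stats::runif(n_out * n_features(ds)) < 0.5),
        n_out, n_features(ds))
    }
    list(dataset = ds, outlier_indices = idx)
  })
}
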