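#' Configuration for the GA rejection layer
#'
#' The rejection layer evolves a binary inlier mask over training rows.
#' Genetic operator probabilities reuse the tuned selection-layer values
#' (0.8 / 0.9 / 0.01); the removal cap, per-class retention floor and the
#' removal penalty are package choices documented in the methods vignette.
#'
#' @param pop_size population size (default 30).
#' @param p_sel roulette gate probability (default 0.8).
#' @param p_cross one-point crossover probability (default 0.9).
#' @param p_mut per-bit flip probability (default 0.01) — note the row
#'   masks mutate per bit, unlike the feature masks' single-bit rule,
#'   because row masks are long and near-saturated.
#' @param max_it number of GA generations (default 40).
#' @param max_removal_fraction largest tolerated fraction of rows removed
#'   (default 0.10); masks beyond it are infeasible.
#' @param min_per_class every class must retain at least this many rows
#'   (default 2).
#' @param penalty_weight weight lambda of the removed-fraction penalty in
#'   the fitness (default 0.5).
#' @param eval_folds internal CV folds for the fitness (default 3).
#' @param seed integer seed.
#' @return an `or_config` list.
#' @export
or_config <- function(pop_size = 30, p_sel = 0.8, p_cross = 0.9,
                      p_mut = 0.01, max_it = 40,
                      max_removal_fraction = 0.10, min_per_class = 2,
                      penalty_weight = 0.5, eval_folds = 3, seed = 1) {
  for (p in c(p_sel, p_cross, p_mut)) {
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  }
  if (max_it < 1) stopf("max_it must be >= 1")
  structure(list(pop_size = as.integer(pop_size), p_sel = p_sel,
                 p_cross = p_cross, p_mut = p_mut,
                 max_it = as.integer(max_it),
                 max_removal_fraction = max_removal_fraction,
                 min_per_class = as.integer(min_per_class),
                 penalty_weight = penalty_weight,
                 eval_folds = as.integer(eval_folds),
                 seed = as.integer(seed)),
            class = "or_config")
}

#' Build the cached inlier-mask fitness function
#'
#' The fitness of an inlier mask is the cross-validated naive-Bayes accuracy
#' of the retained rows (all features) minus
#' `penalty_weight * fraction removed`; the penalty blocks the degenerate
#' strategy of deleting every hard case. Masks removing more than
#' `max_removal_fraction` of rows, or starving any class below
#' `min_per_class` rows, are infeasible and score 0. Fold assignment is
#' fixed from `config$seed`, and values are memoised by mask.
#'
#' @param ds a `symptom_dataset`.
#' @param config an [or_config()].
#' @return function(mask) -> fitness.
#' @export
inlier_fitness_fn <- function(ds, config = or_config()) {
  stopifnot(inherits(ds, "symptom_dataset"))
  n <- n_cases(ds)
  fold_seed <- derive_seed(config$seed, "rl_folds")
  cache <- new.env(parent = emptyenv())
  function(mask) {
    mask <- as.integer(mask)
    if (length(mask) != n) stopf("mask length (%d) != case count (%d)",
                                 length(mask), n)
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    removed_frac <- 1 - sum(mask) / n
    kept <- which(mask == 1L)
    feasible <- removed_frac <= config$max_removal_fraction + 1e-12 &&
      length(kept) > 0 &&
      all(table(factor(ds$labels[kept], levels = unique(ds$labels))) >=
            config$min_per_class)
    val <- 0
    if (feasible) {
      sub <- remove_rows(ds, setdiff(seq_len(n), kept))
      acc <- fitness_accuracy(rep(1L, n_features(sub)), sub,
                              eval_folds = config$eval_folds,
                              seed = fold_seed)
      val <- max(0, acc - config$penalty_weight * removed_frac)
    }
    cache[[key]] <- val
    val
  }
}

#' Fitness of a single inlier mask
#'
#' One-shot wrapper around [inlier_fitness_fn()].
#'
#' @param mask 0/1 vector over rows (1 = keep).
#' @param ds a `symptom_dataset`.
#' @param config an [or_config()].
#' @return fitness value (0 for infeasible masks).
#' @export
inlier_fitness <- function(mask, ds, config = or_config()) {
  inlier_fitness_fn(ds, config)(mask)
}

#' Rejection layer: GA-based outlier removal
#'
#' Evolves inlier masks over the rows of `ds` with roulette selection,
#' one-point crossover, per-bit flip mutation and elitism of 1, then drops
#' the rows excluded by the best mask found. The initial population starts
#' near "keep everything" (bits Bernoulli(0.95), plus the all-ones mask as
#' the first individual, so zero removal is always reachable).
#' Deterministic given `config$seed`.
#'
#' @param ds a `symptom_dataset`.
#' @param config an [or_config()].
#' @return list with `dataset` (filtered), `removed_indices` (sorted row
#'   indices dropped), `best_fitness` and `history` (best-so-far fitness
#'   per generation, non-decreasing).
#' @export
reject_outliers <- function(ds, config = or_config()) {
  stopifnot(inherits(ds, "symptom_dataset"), inherits(config, "or_config"))
  n <- n_cases(ds)
  fitness_fn <- inlier_fitness_fn(ds, config)
  res <- with_seed(derive_seed(config$seed, "rl_search"), {
    pop <- vector("list", config$pop_size)
    pop[[1]] <- list(mask = rep(1L, n), fitness = NA_real_)
    for (i in 2:config$pop_size) {
      bits <- as.integer(stats::runif(n) < 0.95)
      if (sum(bits) == 0) bits[sample.int(n, 1)] <- 1L
      pop[[i]] <- list(mask = bits, fitness = NA_real_)
    }
    pop <- lapply(pop, function(p) { p$fitness <- fitness_fn(p$mask); p })
    best <- pop[[best_or_index(pop)]]
    history <- numeric(0)
    for (gen in seq_len(config$max_it)) {
      offspring <- vector("list", 0)
      while (length(offspring) < config$pop_size) {
        par <- roulette_select(pop, config$p_sel)
        kids <- one_point_crossover(pop[[par[1]]]$mask, pop[[par[2]]]$mask,
                                    config$p_cross)
        for (kid in kids) {
          if (length(offspring) >= config$pop_size) break
          flip <- stats::runif(n) < config$p_mut
          kid[flip] <- 1L - kid[flip]
          if (sum(kid) == 0) kid[sample.int(n, 1)] <- 1L
          offspring[[length(offspring) + 1]] <-
            list(mask = kid, fitness = fitness_fn(kid))
        }
      }
      pop <- apply_elitism(offspring, best)
      cand <- pop[[best_or_index(pop)]]
      if (cand$fitness > best$fitness) best <- cand
      history <- c(history, best$fitness)
    }
    list(best = best, history = history)
  })
  removed <- which(res$best$mask == 0L)
  out_ds <- if (length(removed) > 0) remove_rows(ds, removed) else ds
  list(dataset = out_ds, removed_indices = removed,
       best_fitness = res$best$fitness, history = res$history)
}

# best index for row-mask players: ties toward fewer removals (more ones)
best_or_index <- function(pop) {
  fit <- vapply(pop, `[[`, numeric(1), "fitness")
  ones <- vapply(pop, function(p) sum(p$mask), numeric(1))
  order(-fit, -ones)[1]
}
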