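#' Configuration for the accurate-stage hybrid optimizer
#'
#' Parameter defaults follow the study's tuned values: selection, crossover
#' and mutation probabilities 0.8 / 0.9 / 0.01 for the genetic half;
#' ball-reflection magnitude C1 = 1.2, attraction coefficients C2 = 2.5 and
#' C3 = 1, ball-loss likelihood epsilon = 0.2 for the Tiki-Taka half; and a
#' budget of max_it = 200 cycles. The `patience` early stop and population
#' size are package choices (the source leaves them open).
#'
#' @param pop_size number of chromosomes/players (default 30).
#' @param p_sel probability that a parent pair is drawn by roulette wheel
#'   rather than uniformly (default 0.8).
#' @param p_cross one-point crossover probability (default 0.9).
#' @param p_mut probability that a single uniformly chosen bit is flipped
#'   (default 0.01).
#' @param c1 ball reflection magnitude on an unsuccessful pass, in
#'   [0.5, 1.5] (default 1.2).
#' @param c2 attraction toward the ball, in [1, 2.5] (default 2.5).
#' @param c3 attraction toward the key player, in [0.5, 1.5] (default 1).
#' @param epsilon probability of losing the ball, in [0.1, 0.3]
#'   (default 0.2).
#' @param max_it maximum number of cycles (default 200).
#' @param patience stop after this many cycles without best-fitness
#'   improvement (default 30).
#' @param transfer_rule "as_printed" sets a bit when the uniform draw is
#'   >= sigmoid(position) — the literal published rule; "conventional"
#'   uses the usual < comparison.
#' @param eval_folds internal CV folds for the wrapper fitness (default 3).
#' @param seed integer seed; all search randomness derives from it.
#' @return an `hoa_config` list.
#' @export
hoa_config <- function(pop_size = 30, p_sel = 0.8, p_cross = 0.9,
                       p_mut = 0.01, c1 = 1.2, c2 = 2.5, c3 = 1,
                       epsilon = 0.2, max_it = 200, patience = 30,
                       transfer_rule = c("as_printed", "conventional"),
                       eval_folds = 3, seed = 1) {
  transfer_rule <- match.arg(transfer_rule)
  for (p in c(p_sel, p_cross, p_mut)) {
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  }
  if (max_it < 1) stopf("max_it must be >= 1")
  if (pop_size < 2) stopf("pop_size must be >= 2")
  structure(list(pop_size = as.integer(pop_size), p_sel = p_sel,
                 p_cross = p_cross, p_mut = p_mut, c1 = c1, c2 = c2,
                 c3 = c3, epsilon = epsilon, max_it = as.integer(max_it),
                 patience = as.integer(patience),
                 transfer_rule = transfer_rule,
                 eval_folds = as.integer(eval_folds),
                 seed = as.integer(seed)),
            class = "hoa_config")
}

new_player <- function(mask, fitness = NA_real_) {
  mask <- as.integer(mask)
  list(mask = mask, position = as.numeric(mask),
       ball = as.numeric(mask), fitness = fitness)
}

#' Initialise a random population of players
#'
#' Each mask bit is i.i.d. Bernoulli(0.5); all-zero masks are resampled.
#' Continuous positions and balls start as the 0/1 mask values. Consumes the
#' current RNG stream (seed at the call site for reproducibility).
#'
#' @param c population size (>= 2).
#' @param v mask length (>= 1).
#' @return list of players, each with `mask`, `position`, `ball`, `fitness`.
#' @export
init_population <- function(c, v) {
  stopifnot(c >= 2, v >= 1)
  lapply(seq_len(c), function(i) {
    repeat {
      bits <- as.integer(stats::runif(v) < 0.5)
      if (sum(bits) > 0) break
    }
    new_player(bits)
  })
}

#' Roulette-wheel parent selection
#'
#' With probability `p_sel` draws two parents independently with probability
#' proportional to fitness (uniform fallback when all fitness values are 0);
#' otherwise the pair is drawn uniformly.
#'
#' @param pop list of evaluated players.
#' @param p_sel gate probability for fitness-proportional selection.
#' @return integer vector of two parent indices (may coincide).
#' @export
roulette_select <- function(pop, p_sel = 0.8) {
  fit <- vapply(pop, `[[`, numeric(1), "fitness")
  if (any(fit < 0)) stopf("roulette selection requires non-negative fitness")
  n <- length(pop)
  if (stats::runif(1) < p_sel && sum(fit) > 0) {
    sample.int(n, 2, replace = TRUE, prob = fit / sum(fit))
  } else {
    sample.int(n, 2, replace = TRUE)
  }
}

#' One-point crossover of two feature masks
#'
#' With probability `p_cross` a cut point is drawn uniformly in
#' `1..(v - 1)` and the suffixes are swapped; otherwise the parents are
#' returned unchanged.
#'
#' @param a,b 0/1 vectors of equal length >= 2.
#' @param p_cross crossover probability.
#' @return list of two child masks.
#' @export
one_point_crossover <- function(a, b, p_cross = 0.9) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stopf("parent length mismatch")
  v <- length(a)
  if (v >= 2 && stats::runif(1) < p_cross) {
    k <- sample.int(v - 1, 1)
    tail_idx <- (k + 1):v
    tmp <- a[tail_idx]
    a[tail_idx] <- b[tail_idx]
    b[tail_idx] <- tmp
  }
  list(a, b)
}

#' Single-bit flip mutation
#'
#' With probability `p_mut` flips exactly one uniformly chosen bit. If the
#' flip empties the mask, one additional uniformly chosen bit is set back
#' to 1 so every candidate keeps at least one feature.
#'
#' @param m 0/1 vector.
#' @param p_mut mutation probability.
#' @return mutated 0/1 vector.
#' @export
bit_flip_mutation <- function(m, p_mut = 0.01) {
  m <- as.integer(m)
  if (stats::runif(1) < p_mut) {
    i <- sample.int(length(m), 1)
    m[i] <- 1L - m[i]
    if (sum(m) == 0) m[sample.int(length(m), 1)] <- 1L
  }
  m
}

evaluate_player <- function(pl, fitness_fn) {
  pl$fitness <- fitness_fn(pl$mask)
  pl
}

best_index <- function(pop) {
  fit <- vapply(pop, `[[`, numeric(1), "fitness")
  pc <- vapply(pop, function(p) sum(p$mask), numeric(1))
  order(-fit, pc)[1]
}

# elitism: reinsert the incumbent best over the worst offspring if its mask
# is absent from the new population
apply_elitism <- function(new_pop, incumbent) {
  key <- paste(incumbent$mask, collapse = "")
  present <- any(vapply(new_pop, function(p)
    paste(p$mask, collapse = "") == key, logical(1)))
  if (!present) {
    fit <- vapply(new_pop, `[[`, numeric(1), "fitness")
    new_pop[[which.min(fit)]] <- incumbent
  }
  new_pop
}

#' One genetic-algorithm generation over feature masks
#'
#' Repeats roulette selection, one-point crossover and single-bit mutation,
#' appending offspring until the population size is restored; every offspring
#' is evaluated, and the incumbent best is reinserted over the worst
#' offspring if its mask did not survive (elitism of 1).
#'
#' @param pop list of evaluated players.
#' @param config an [hoa_config()].
#' @param fitness_fn mask -> fitness closure, e.g. from [nb_fitness_fn()].
#' @return new list of evaluated players of the same size.
#' @export
ga_generation <- function(pop, config, fitness_fn) {
  c <- length(pop)
  incumbent <- pop[[best_index(pop)]]
  offspring <- vector("list", 0)
  while (length(offspring) < c) {
    par <- roulette_select(pop, config$p_sel)
    kids <- one_point_crossover(pop[[par[1]]]$mask, pop[[par[2]]]$mask,
                                config$p_cross)
    for (kid in kids) {
      if (length(offspring) >= c) break
      kid <- bit_flip_mutation(kid, config$p_mut)
      if (sum(kid) == 0) kid[sample.int(length(kid), 1)] <- 1L
      offspring[[length(offspring) + 1]] <-
        evaluate_player(new_player(kid), fitness_fn)
    }
  }
  apply_elitism(offspring, incumbent)
}

#' Tiki-Taka ball-position update
#'
#' One `rand_p` draw decides whether the pass succeeds (`rand_p > epsilon`);
#' per-dimension draws `r` in (0, 1] then move the ball along the distance to
#' the cyclic neighbour's ball: forward continuation on success, reflection
#' scaled by `C1 + r` on a lost ball.
#'
#' @param ball_i current ball position (numeric vector).
#' @param ball_next neighbouring ball position (same length).
#' @param config an [hoa_config()].
#' @return updated ball position.
#' @export
update_ball <- function(ball_i, ball_next, config) {
  if (length(ball_i) != length(ball_next)) stopf("ball length mismatch")
  rand_p <- stats::runif(1)
  r <- runif_01(length(ball_i))
  d <- ball_i - ball_next
  if (rand_p > config$epsilon) {
    r * d + ball_i
  } else {
    ball_i - (config$c1 + r) * d
  }
}

#' Tiki-Taka player-position update
#'
#' Moves a player toward its ball and toward the key player:
#' `pl + r * C2 * (ball - pl) + r * C3 * (q - pl)`, with `r` drawn uniformly
#' in (0, 1] per dimension.
#'
#' @param pl current player position (numeric vector).
#' @param ball the player's ball position.
#' @param q the key (best) player's position.
#' @param config an [hoa_config()].
#' @return updated position.
#' @export
update_player <- function(pl, ball, q, config) {
  if (length(pl) != length(ball) || length(pl) != length(q)) {
    stopf("position length mismatch")
  }
  r <- runif_01(length(pl))
  pl + r * config$c2 * (ball - pl) + r * config$c3 * (q - pl)
}

#' Logistic transfer function
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`, elementwise.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binarize a continuous position through the sigmoid transfer
#'
#' Per dimension a uniform `r` in [0, 1] is drawn and compared with
#' `sigmoid(value)`. The `as_printed` rule sets the bit when
#' `r >= sigmoid(value)`, exactly as published (note this makes large
#' positive coordinates unlikely to be selected); `conventional` uses the
#' standard `r < sigmoid(value)`. An all-zero outcome is repaired by setting
#' one uniformly chosen bit.
#'
#' @param values numeric vector of positions.
#' @param rule "as_printed" or "conventional".
#' @return integer 0/1 mask with popcount >= 1.
#' @export
binarize <- function(values, rule = c("as_printed", "conventional")) {
  rule <- match.arg(rule)
  r <- stats::runif(length(values))
  s <- sigmoid(values)
  bits <- if (rule == "as_printed") as.integer(r >= s) else as.integer(r < s)
  if (sum(bits) == 0) bits[sample.int(length(bits), 1)] <- 1L
  bits
}

#' One Tiki-Taka generation over feature masks
#'
#' Positions and balls are (re)seeded from the incoming binary masks, the key
#' player `q` is the max-fitness position, every ball is passed toward its
#' cyclic neighbour's ball, every player moves toward its new ball and `q`,
#' positions are binarized through the sigmoid transfer, and offspring are
#' evaluated; elitism reinserts the incumbent best as in [ga_generation()].
#'
#' @inheritParams ga_generation
#' @return new list of evaluated players of the same size.
#' @export
tta_generation <- function(pop, config, fitness_fn) {
  c <- length(pop)
  pop <- lapply(pop, function(p) {
    p$position <- as.numeric(p$mask)
    p$ball <- as.numeric(p$mask)
    p
  })
  incumbent <- pop[[best_index(pop)]]
  q <- pop[[best_index(pop)]]$position
  balls <- lapply(pop, `[[`, "ball")
  new_pop <- vector("list", c)
  for (i in seq_len(c)) {
    nb <- balls[[if (i == c) 1 else i + 1]]
    ball_new <- update_ball(balls[[i]], nb, config)
    pos_new <- update_player(pop[[i]]$position, ball_new, q, config)
    mask_new <- binarize(pos_new, config$transfer_rule)
    pl <- list(mask = mask_new, position = pos_new, ball = ball_new,
               fitness = NA_real_)
    new_pop[[i]] <- evaluate_player(pl, fitness_fn)
  }
  apply_elitism(new_pop, incumbent)
}

#' Accurate stage: wrapper feature selection by the hybrid optimizer
#'
#' Runs the fast chi-square stage down to `v` features, then searches the
#' reduced space with the hybrid scheme: each cycle performs one GA
#' generation whose output population feeds one Tiki-Taka generation, whose
#' output feeds the next cycle. `ga_only` and `tta_only` run the same budget
#' with a single generation type per cycle (ablations). Fitness is the
#' cross-validated naive-Bayes accuracy of the candidate subset
#' ([nb_fitness_fn()]). Stops after `max_it` cycles or `patience` cycles
#' without improvement of the best fitness. Fully deterministic given
#' `config$seed`.
#'
#' @param train a `symptom_dataset`.
#' @param method "hfsa" (alternating GA + Tiki-Taka), "ga_only" or
#'   "tta_only".
#' @param v fast-stage survivor count or fraction (see [run_fast_stage()]).
#' @param config an [hoa_config()].
#' @return a `selection_result` list: `best_mask` (0/1 over the `v`
#'   filtered features), `best_fitness`, `kept_original_indices` (selected
#'   columns of the input dataset), `selected_features` (their names),
#'   `history` (best-so-far fitness per cycle), `fs_kept_indices`,
#'   `scores` (fast-stage chi-square scores), `method` and `m`
#'   (final subset size).
#' @export
select_features <- function(train, method = c("hfsa", "ga_only", "tta_only"),
                            v = 0.5, config = hoa_config()) {
  method <- match.arg(method)
  stopifnot(inherits(train, "symptom_dataset"), inherits(config, "hoa_config"))
  fs <- run_fast_stage(train, v)
  reduced <- fs$dataset
  fitness_fn <- nb_fitness_fn(reduced, config$eval_folds,
                              derive_seed(config$seed, "fitness"))
  res <- with_seed(derive_seed(config$seed, "search"), {
    pop <- lapply(init_population(config$pop_size, n_features(reduced)),
                  evaluate_player, fitness_fn = fitness_fn)
    bi <- best_index(pop)
    best <- pop[[bi]]
    history <- numeric(0)
    stall <- 0L
    for (cycle in seq_len(config$max_it)) {
      if (method %in% c("hfsa", "ga_only")) {
        pop <- ga_generation(pop, config, fitness_fn)
      }
      if (method %in% c("hfsa", "tta_only")) {
        pop <- tta_generation(pop, config, fitness_fn)
      }
      cand <- pop[[best_index(pop)]]
      improved <- cand$fitness > best$fitness ||
        (cand$fitness == best$fitness && sum(cand$mask) < sum(best$mask))
      if (cand$fitness > best$fitness) stall <- 0L else stall <- stall + 1L
      if (improved) best <- cand
      history <- c(history, best$fitness)
      if (stall >= config$patience) break
    }
    list(best = best, history = history)
  })
  kept <- fs$kept_indices[res$best$mask == 1L]
  structure(list(best_mask = feature_mask(res$best$mask),
                 best_fitness = res$best$fitness,
                 kept_original_indices = kept,
                 selected_features = train$feature_names[kept],
                 history = res$history,
                 fs_kept_indices = fs$kept_indices,
                 scores = fs$scores,
                 method = method,
                 m = sum(res$best$mask)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d features selected, fitness %.4f after %d cycles\n",
              x$method, x$m, x$best_fitness, length(x$history)))
  invisible(x)
}

#' Exhaustive feature-subset oracle
#'
#' Enumerates every nonempty mask over up to 12 features and returns the
#' global fitness maximum; ties are broken toward smaller popcount, then
#' toward the mask enumerated first (bits as a binary integer). Intended as
#' an independent reference for the heuristic search.
#'
#' @param train a `symptom_dataset` with at most 12 features.
#' @param fitness_fn mask -> fitness closure.
#' @return list with `best_mask` (0/1) and `best_fitness`.
#' @export
exhaustive_oracle <- function(train, fitness_fn) {
  v <- n_features(train)
  if (v > 12) stopf("exhaustive oracle limited to 12 features (got %d)", v)
  n_masks <- 2^v - 1
  fits <- numeric(n_masks)
  pops <- integer(n_masks)
  masks <- vector("list", n_masks)
  for (i in seq_len(n_masks)) {
    bits <- as.integer(intToBits(i))[seq_len(v)]
    masks[[i]] <- bits
    pops[i] <- sum(bits)
    fits[i] <- fitness_fn(bits)
  }
  j <- order(-fits, pops, seq_len(n_masks))[1]
  list(best_mask = feature_mask(masks[[j]]), best_fitness = fits[j])
}
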