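test_that("init_population: sizes, nonzero masks, determinism, bit frequency", {
  pop1 <- hfsa:::with_seed(5, init_population(30, 20))
  pop2 <- hfsa:::with_seed(5, init_population(30, 20))
  expect_length(pop1, 30)
  expect_identical(pop1, pop2)
  expect_true(all(vapply(pop1, function(p) sum(p$mask) > 0, logical(1))))
  expect_true(all(vapply(pop1, function(p)
    identical(p$position, as.numeric(p$mask)), logical(1))))
  big <- hfsa:::with_seed(6, init_population(200, 50))
  freq <- mean(unlist(lapply(big, `[[`, "mask")))
  se3 <- 3 * sqrt(0.25 / (200 * 50))
  expect_lt(abs(freq - 0.5), se3 + 0.01)  # + all-zero resampling slack
})

test_that("roulette selection is fitness-proportional", {
  pop <- list(list(mask = c(1L, 0L), fitness = 1),
              list(mask = c(0L, 1L), fitness = 3))
  draws <- hfsa:::with_seed(7, {
    unlist(lapply(1:5000, function(i) roulette_select(pop, p_sel = 1)))
  })
  # expected frequencies 0.25 / 0.75; chi-square GOF at alpha = 0.01
  obs <- tabulate(draws, 2)
  pval <- stats::chisq.test(obs, p = c(0.25, 0.75))$p.value
  expect_gt(pval, 0.01)
  # all-equal fitness => uniform
  pop_eq <- list(list(mask = 1L, fitness = 1), list(mask = 1L, fitness = 1),
                 list(mask = 1L, fitness = 1))
  draws_eq <- hfsa:::with_seed(8, {
    unlist(lapply(1:6000, function(i) roulette_select(pop_eq, p_sel = 1)))
  })
  pval_eq <- stats::chisq.test(tabulate(draws_eq, 3))$p.value
  expect_gt(pval_eq, 0.01)
})

test_that("one-point crossover swaps suffixes and conserves loci", {
  a <- c(1L, 1L, 0L, 0L)
  b <- c(0L, 0L, 1L, 1L)
  cuts <- list(`1` = list(c(1, 0, 1, 1), c(0, 1, 0, 0)),
               `2` = list(c(1, 1, 1, 1), c(0, 0, 0, 0)),
               `3` = list(c(1, 1, 0, 1), c(0, 0, 1, 0)))
  seen <- character(0)
  hfsa:::with_seed(9, {
    for (i in 1:60) {
      kids <- one_point_crossover(a, b, p_cross = 1)
      hit <- which(vapply(cuts, function(ct)
        identical(kids[[1]], as.integer(ct[[1]])) &&
          identical(kids[[2]], as.integer(ct[[2]])), logical(1)))
      expect_length(hit, 1)  # every child pair is a valid suffix swap
      seen <- c(seen, names(cuts)[hit])
      for (loc in 1:4) {
        expect_true(kids[[1]][loc] %in% c(a[loc], b[loc]))
        expect_true(kids[[2]][loc] %in% c(a[loc], b[loc]))
      }
    }
  })
  expect_setequal(unique(seen), c("1", "2", "3"))
  # includes the spec's cut-after-2 case: 1100 x 0011 -> 1111 / 0000
  expect_true("2" %in% seen)
  # gate off: children are copies
  hfsa:::with_seed(10, {
    kids0 <- one_point_crossover(a, b, p_cross = 0)
    expect_identical(kids0[[1]], a)
    expect_identical(kids0[[2]], b)
  })
  expect_error(one_point_crossover(c(1L, 0L), c(1L, 0L, 1L), 1), "mismatch")
})

test_that("bit-flip mutation fires at rate p_mut, moves Hamming distance 1", {
  m <- c(1L, 0L, 1L, 0L, 1L)
  hfsa:::with_seed(11, {
    expect_identical(bit_flip_mutation(m, 0), m)
    fires <- 0
    for (i in 1:10000) {
      out <- bit_flip_mutation(m, 0.01)
      d <- sum(out != m)
      expect_true(d %in% c(0L, 1L))
      if (d > 0) fires <- fires + 1
    }
    se3 <- 3 * sqrt(10000 * 0.01 * 0.99)
    expect_lt(abs(fires - 100), se3)
    # all-zero repair: flipping the single 1 re-sets some bit
    out1 <- bit_flip_mutation(c(1L), 1)
    expect_identical(out1, c(1L))
  })
})

test_that("update_ball follows both branches of the passing rule", {
  cfg <- hoa_config(c1 = 1.2, epsilon = 0.2)
  # zero distance: output = ball under either branch
  hfsa:::with_seed(12, {
    expect_equal(update_ball(c(2, 2), c(2, 2), cfg), c(2, 2))
  })
  # force branches via epsilon: epsilon = 0 => always successful pass
  succ <- hoa_config(c1 = 1.2, epsilon = 0)
  hfsa:::with_seed(13, {
    out <- update_ball(2, 1, succ)   # r * (2 - 1) + 2, r in (0, 1]
    expect_true(out > 2 && out <= 3)
  })
  # epsilon = 1 => always unsuccessful: 2 - (1.2 + r) * 1 in [0.3 - eps, 0.8)
  fail <- hoa_config(c1 = 1.2, epsilon = 1)
  hfsa:::with_seed(14, {
    out <- update_ball(2, 1, fail)
    expect_true(out >= 2 - 2.2 && out < 2 - 1.2)
  })
  # closed-form checks at r = 1 (success) and r = 0.5 (failure)
  expect_equal(1 * (2 - 1) + 2, 3.0)
  expect_equal(2 - (1.2 + 0.5) * (2 - 1), 0.3)
  expect_error(update_ball(c(1, 2), 1, cfg), "mismatch")
})

test_that("update_player moves between its r -> 0 and r -> 1 limits", {
  cfg <- hoa_config(c2 = 2.5, c3 = 1)
  hfsa:::with_seed(15, {
    expect_equal(update_player(c(1, 1), c(1, 1), c(1, 1), cfg), c(1, 1))
    # closed form at r = 1: 0 + 2.5 * 1 + 1 * 1 = 3.5
    expect_equal(0 + 1 * 2.5 * (1 - 0) + 1 * 1 * (1 - 0), 3.5)
    for (i in 1:50) {
      out <- update_player(0, 1, 1, cfg)
      expect_true(out > 0 & out <= 3.5)  # between pl and the r = 1 limit
    }
  })
})

test_that("sigmoid identities and binarization transfer rules hold", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-3, -0.5, 0.7, 4)
  expect_equal(sigmoid(-x), 1 - sigmoid(x), tolerance = 1e-12)
  expect_gt(sigmoid(50), 1 - 1e-9)

  # saturation + rule direction (second coord avoids the all-zero repair)
  hfsa:::with_seed(16, {
    printed <- replicate(400, binarize(c(50, -50), "as_printed")[1])
    conv <- replicate(400, binarize(c(50, -50), "conventional")[2])
    expect_equal(mean(printed), 0)
    expect_equal(mean(conv), 0)
    # empirical frequency matches 1 - sigmoid(v) under as_printed
    grid <- c(-50, -1.5, -0.5, 0, 0.5, 1.5)
    bits <- replicate(4000, binarize(grid, "as_printed"))
    freq <- rowMeans(bits)
    expected <- 1 - sigmoid(grid)
    se3 <- 3 * sqrt(expected * (1 - expected) / 4000)
    expect_true(all(abs(freq - expected) <= se3 + 1e-6))
    # all-zero repair guarantees popcount >= 1
    expect_gte(sum(binarize(c(50, 50, 50), "as_printed")), 1)
  })
})

test_that("ga_generation keeps size, applies elitism, fixes points", {
  gen <- noiseless_ds(seed = 17)
  ds <- gen$dataset
  ff <- nb_fitness_fn(ds, 3, 1)
  hfsa:::with_seed(18, {
    pop <- lapply(init_population(10, n_features(ds)),
                  function(p) { p$fitness <- ff(p$mask); p })
    best_before <- max(vapply(pop, `[[`, numeric(1), "fitness"))
    for (g in 1:10) {
      pop <- ga_generation(pop, hoa_config(pop_size = 10), ff)
      expect_length(pop, 10)
      best_now <- max(vapply(pop, `[[`, numeric(1), "fitness"))
      expect_gte(best_now, best_before)
      best_before <- best_now
    }
    # clones of one mask with p_mut = 0 are a fixed point
    clone <- lapply(1:6, function(i) {
      p <- hfsa:::new_player(rep(1L, n_features(ds)))
      p$fitness <- ff(p$mask)
      p
    })
    out <- ga_generation(clone, hoa_config(pop_size = 6, p_mut = 0), ff)
    expect_true(all(vapply(out, function(p)
      identical(p$mask, clone[[1]]$mask), logical(1))))
  })
})

test_that("tta_generation: elitism, determinism, degenerate single norms", {
  gen <- small_benchmark(seed = 19, n_diseases = 4, n_features = 16,
                         cases = 15)
  ds <- gen$dataset
  ff <- nb_fitness_fn(ds, 3, 2)
  cfg <- hoa_config(pop_size = 8)
  run_once <- function(seed) {
    hfsa:::with_seed(seed, {
      pop <- lapply(init_population(8, n_features(ds)),
                    function(p) { p$fitness <- ff(p$mask); p })
      best <- max(vapply(pop, `[[`, numeric(1), "fitness"))
      for (g in 1:20) {
        pop <- tta_generation(pop, cfg, ff)
        now <- max(vapply(pop, `[[`, numeric(1), "fitness"))
        expect_gte(now, best)
        best <- now
      }
      pop
    })
  }
  a <- run_once(20)
  b <- run_once(20)
  expect_identical(a, b)
  expect_false(identical(a, run_once(21)))
  # masks stay binary, nonzero, length v throughout
  expect_true(all(vapply(a, function(p)
    length(p$mask) == n_features(ds) && sum(p$mask) >= 1 &&
      all(p$mask %in% c(0L, 1L)), logical(1))))
})

test_that("select_features finds the planted optimum and keeps tidy history", {
  gen <- noiseless_ds(n_diseases = 3, n_features = 20, informative = 1,
                      cases = 12, seed = 23)
  ds <- gen$dataset
  cfg <- hoa_config(pop_size = 14, max_it = 25, patience = 25, seed = 3)
  res <- select_features(ds, "hfsa", v = 10, config = cfg)
  expect_s3_class(res, "selection_result")
  expect_equal(res$best_fitness, 1.0)
  expect_false(is.unsorted(res$history))
  expect_equal(res$best_fitness, max(res$history))
  expect_equal(res$m, sum(res$best_mask))
  expect_lte(res$m, 10)
  # selected indices map back through the fast stage
  expect_true(all(res$kept_original_indices %in% res$fs_kept_indices))
  expect_identical(res$selected_features,
                   ds$feature_names[res$kept_original_indices])
  # full determinism of the result object
  expect_identical(select_features(ds, "hfsa", v = 10, config = cfg), res)
})

test_that("ablations run under the same budget and remain deterministic", {
  gen <- small_benchmark(seed = 29, n_diseases = 4, n_features = 16,
                         cases = 15)
  cfg <- hoa_config(pop_size = 10, max_it = 8, patience = 8, seed = 5)
  for (method in c("ga_only", "tta_only")) {
    r1 <- select_features(gen$dataset, method, v = 8, config = cfg)
    r2 <- select_features(gen$dataset, method, v = 8, config = cfg)
    expect_identical(r1, r2)
    expect_false(is.unsorted(r1$history))
    expect_gte(r1$best_fitness, 0)
  }
})

test_that("exhaustive oracle enumerates all masks and dominates heuristics", {
  ds <- random_ds(n = 30, u = 3, k = 2, seed = 37)
  calls <- new.env(); calls$n <- 0
  ff <- nb_fitness_fn(ds, 3, 1)
  counting_ff <- function(mask) { calls$n <- calls$n + 1; ff(mask) }
  oracle <- exhaustive_oracle(ds, counting_ff)
  expect_equal(calls$n, 7)  # 2^3 - 1 nonempty masks
  expect_gte(sum(oracle$best_mask), 1)
  # oracle fitness >= any candidate's fitness
  for (i in 1:7) {
    bits <- as.integer(intToBits(i))[1:3]
    expect_gte(oracle$best_fitness, ff(bits))
  }
  expect_error(exhaustive_oracle(random_ds(u = 13, seed = 1), ff), "12")
})
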