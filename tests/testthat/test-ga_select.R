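test_that("ga_config enforces its invariants", {
  expect_s3_class(ga_config(), "ga_config")
  expect_error(ga_config(population_size = 1L, elite_size = 0L,
                         offspring_size = 1L), "population_size")
  expect_error(ga_config(population_size = 10L, elite_size = 3L,
                         offspring_size = 6L), "equal population_size")
  expect_error(ga_config(population_size = 10L, elite_size = 5L,
                         offspring_size = 5L), "even")
  expect_error(ga_config(mutation_rate = 1.5), "mutation_rate")
})

test_that("initial population is all-ones, then singletons, then random", {
  cfg <- ga_config(population_size = 6L, elite_size = 2L,
                   offspring_size = 4L, seed = 1L)
  pop <- withr::with_seed(1L, init_population(3L, cfg))
  expect_length(pop, 6L)
  expect_equal(pop[[1]], c(1L, 1L, 1L))
  expect_equal(pop[[2]], c(1L, 0L, 0L))
  expect_equal(pop[[3]], c(0L, 1L, 0L))
  expect_equal(pop[[4]], c(0L, 0L, 1L))
  expect_true(all(vapply(pop[5:6], function(g) all(g %in% 0:1), logical(1))))
  # seeded reproducibility
  pop2 <- withr::with_seed(1L, init_population(3L, cfg))
  expect_identical(pop, pop2)
  # deterministic part truncated when it exceeds the population
  cfg_small <- ga_config(population_size = 4L, elite_size = 2L,
                         offspring_size = 2L)
  pop3 <- withr::with_seed(1L, init_population(10L, cfg_small))
  expect_length(pop3, 4L)
  expect_equal(pop3[[1]], rep(1L, 10L))
  expect_equal(which(pop3[[3]] == 1L), 2L)
})

test_that("single-point crossover exchanges tails and conserves bits", {
  ch <- ga_crossover(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L), cut = 2L)
  expect_equal(ch[[1]], c(1L, 1L, 1L, 1L))
  expect_equal(ch[[2]], c(0L, 0L, 0L, 0L))
  same <- ga_crossover(c(1L, 0L, 1L), c(1L, 0L, 1L), cut = 1L)
  expect_equal(same[[1]], c(1L, 0L, 1L))
  expect_equal(same[[2]], c(1L, 0L, 1L))
  expect_error(ga_crossover(c(1L, 0L), c(1L, 0L, 1L), 1L), "lengths differ")
  expect_error(ga_crossover(c(1L, 0L), c(0L, 1L), 2L), "cut")
  # bit-count conservation over random pairs
  for (seed in 1:10) {
    withr::with_seed(seed, {
      L <- sample(4:40, 1)
      a <- as.integer(stats::runif(L) < 0.5)
      b <- as.integer(stats::runif(L) < 0.5)
      cut <- sample(L - 1L, 1)
    })
    ch <- ga_crossover(a, b, cut)
    expect_equal(sum(ch[[1]]) + sum(ch[[2]]), sum(a) + sum(b))
  }
})

test_that("point mutation matches its degenerate cases and expected flip count", {
  g <- c(1L, 0L, 1L, 1L, 0L)
  expect_equal(withr::with_seed(1, ga_mutate(g, 0)), g)
  expect_equal(withr::with_seed(1, ga_mutate(g, 1)), 1L - g)
  # Monte-Carlo flip count vs binomial expectation: rate 1e-3 on length
  # 1532 over 10000 genomes -> mean flips/genome 1.532 within 5%
  flips <- withr::with_seed(202L, {
    base <- rep(0L, 1532L)
    vapply(seq_len(10000L), function(i) sum(ga_mutate(base, 1e-3)),
           numeric(1))
  })
  expect_lt(abs(mean(flips) - 1.532) / 1.532, 0.05)
})

test_that("one generation keeps the best genome unaltered and the size fixed", {
  cfg <- ga_config(population_size = 20L, elite_size = 6L,
                   offspring_size = 14L, mutation_rate = 0.05)
  withr::with_seed(3L, {
    pop <- init_population(8L, cfg)
    fit <- vapply(pop, function(g) sum(g), numeric(1))  # toy fitness
    nxt <- step_generation(pop, fit, cfg)
  })
  expect_length(nxt, 20L)
  best <- pop[[which.max(fit)]]
  expect_true(any(vapply(nxt, identical, logical(1), y = best)))
  expect_error(step_generation(pop, fit[-1], cfg), "mismatch")
  # with mutation off, every offspring bit equals one of its parents' bits
  cfg0 <- ga_config(population_size = 20L, elite_size = 6L,
                    offspring_size = 14L, mutation_rate = 0)
  withr::with_seed(4L, {
    nxt0 <- step_generation(pop, fit, cfg0)
  })
  elite_mat <- do.call(rbind, pop[order(-fit)][1:6])
  for (child in nxt0[7:20]) {
    ok <- vapply(seq_along(child), function(j)
      child[j] %in% elite_mat[, j], logical(1))
    expect_true(all(ok))
  }
})

test_that("the GA reaches a perfect subset on the descriptor fixture", {
  dm <- load_descriptor_table()
  cfg <- ga_config(population_size = 500L, elite_size = 100L,
                   offspring_size = 400L, seed = 1L,
                   max_generations = 30L, stall_generations = 5L)
  res <- run_ga(dm, cfg)
  expect_equal(res$best_fitness, 9L)
  expect_true(all(diff(res$history$best) >= 0))  # elitist monotonicity
  expect_lte(res$best_fitness, nrow(dm$values))
  # determinism: identical (matrix, config, seed) -> identical result
  res2 <- run_ga(dm, cfg)
  expect_identical(res$best_subset, res2$best_subset)
  expect_identical(res$history, res2$history)
  # single-class labels rejected
  one <- descriptor_matrix(dm$values,
                           labels = rep("permeant", nrow(dm$values)))
  expect_error(run_ga(one, cfg), "both classes")
})

test_that("the GA recovers planted informative descriptors", {
  gen <- gen_descriptor_dataset(10, 10, 5, 95, effect_size = 3, seed = 7)
  cfg <- ga_config(population_size = 200L, elite_size = 50L,
                   offspring_size = 150L, seed = 2L,
                   max_generations = 40L, stall_generations = 5L)
  res <- run_ga(gen$matrix, cfg)
  expect_equal(res$best_fitness, 20L)
  expect_gte(sum(res$best_subset[gen$informative]), 1L)
})
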