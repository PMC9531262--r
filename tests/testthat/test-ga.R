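test_that("population initialisation respects size and subset bounds", {
  cfg <- ga_config(population_size = 1000, max_features = 15, seed = 1)
  set.seed(1)
  pop <- init_population(cfg, 1200)
  expect_length(pop, 1000)
  sizes <- lengths(lapply(pop, `[[`, "features"))
  expect_true(all(sizes >= 1 & sizes <= 15))
  expect_true(all(unlist(lapply(pop, `[[`, "features")) %in% 1:1200))
  set.seed(1)
  pop2 <- init_population(cfg, 1200)
  expect_identical(pop, pop2)
  expect_error(init_population(cfg, 10), "max_features")
})

test_that("fitness is |Pearson r| between subset PC1 and the target", {
  set.seed(2)
  n <- 50
  y <- rnorm(n)
  vals <- cbind(y, -y, matrix(rnorm(n * 10), n, 10))
  tab <- standardize_features(make_table(vals, y))
  expect_equal(ga_fitness(1L, tab, "target"), 1, tolerance = 1e-9)
  expect_equal(ga_fitness(2L, tab, "target"), 1, tolerance = 1e-9)  # sign-flipped copy
  # invariance to affine target rescale and feature sign flips
  f0 <- ga_fitness(c(3L, 4L), tab, "target")
  expect_equal(ga_fitness(c(3L, 4L), tab, 5 * tab$targets$target - 2), f0,
               tolerance = 1e-9)
  flipped <- tab
  flipped$values[, 3] <- -flipped$values[, 3]
  expect_equal(ga_fitness(c(3L, 4L), flipped, "target"), f0, tolerance = 1e-6)
  # zero-variance submatrix scores 0
  tab0 <- tab
  tab0$values[, 5] <- 0
  expect_equal(ga_fitness(5L, tab0, "target"), 0)
  expect_error(ga_fitness(1L, tab, rep(1, n)), "zero variance")
})

test_that("fitness of random singletons on a pure-noise table is near zero", {
  set.seed(3)
  n <- 200
  tab <- standardize_features(make_table(matrix(rnorm(n * 120), n, 120), rnorm(n)))
  fits <- vapply(sample(120, 100, replace = TRUE),
                 function(j) ga_fitness(j, tab, "target"), numeric(1))
  expect_lt(mean(fits), 0.2)   # E|r| ~ sqrt(2/(pi n)) ~ 0.056 under the null
})

test_that("crossover obeys the three inheritance cases", {
  cfg <- ga_config(seed = 1)
  a <- list(features = c(1L, 2L, 3L), fitness = NA_real_)
  set.seed(4)
  expect_identical(ga_crossover(a, a, cfg)$features, a$features)
  for (i in 1:200) {
    fa <- sample(50, sample(5, 1)); fb <- sample(50, sample(5, 1))
    child <- ga_crossover(list(features = fa), list(features = fb), cfg)$features
    expect_true(all(intersect(fa, fb) %in% child))
    expect_true(all(child %in% union(fa, fb)))
  }
  # disjoint parents: child size ~ Binomial(|a delta b|, 1/2)
  set.seed(5)
  sizes <- replicate(10000, length(
    ga_crossover(list(features = 1:4), list(features = 5:8), cfg)$features))
  expect_lt(abs(mean(sizes) - 4), 0.1)
})

test_that("mutation adds/deletes per-feature and enforces the size cap", {
  quiet_cfg <- ga_config(p_add = 0, p_delete = 0, max_features = 15, seed = 1)
  ind <- list(features = sort(sample(100, 10)))
  set.seed(6)
  expect_identical(ga_mutate(ind, quiet_cfg, 100)$features, ind$features)
  # oversized input with silent rates: uniform cap at 15
  big <- list(features = 1:20)
  set.seed(7)
  counts <- integer(20)
  sizes <- integer(10000)
  for (i in 1:10000) {
    out <- ga_mutate(big, quiet_cfg, 100)$features
    sizes[i] <- length(out)
    counts[out] <- counts[out] + 1
  }
  expect_true(all(sizes == 15))
  # each of the 20 features retained with probability 15/20
  expect_true(all(abs(counts / 10000 - 0.75) < 0.02))
  # active rates still respect bounds
  noisy_cfg <- ga_config(p_add = 0.05, p_delete = 0.5, max_features = 5, seed = 1)
  set.seed(8)
  for (i in 1:500) {
    out <- ga_mutate(list(features = sample(40, 4)), noisy_cfg, 40)$features
    expect_true(length(out) >= 1 && length(out) <= 5)
  }
})

test_that("PC1 scores match closed forms on degenerate subsets", {
  set.seed(9)
  vals <- matrix(rnorm(60 * 6), 60, 6)
  tab <- standardize_features(make_table(vals, rnorm(60)))
  s1 <- pc1_scores(1L, tab)
  expect_equal(abs(s1), abs(tab$values[, 1]), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(abs(mean(s1)), 1e-9)
  # duplicated column: scores proportional with gain sqrt(2)
  tab$values[, 2] <- tab$values[, 1]
  s2 <- pc1_scores(c(1L, 2L), tab)
  expect_equal(abs(s2), sqrt(2) * abs(tab$values[, 1]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("evolution is elitist-monotone, deterministic, and budget-bound", {
  set.seed(10)
  n <- 40
  vals <- matrix(rnorm(n * 30), n, 30)
  y <- vals[, 1] + vals[, 2] + rnorm(n, 0, 0.5)
  tab <- standardize_features(make_table(vals, y))
  cfg <- ga_config(population_size = 30, max_features = 5, generations = 15, seed = 11)
  res <- ga_evolve(tab, "target", cfg)
  expect_s3_class(res, "acg_ga_result")
  expect_equal(res$generations_run, 15)
  expect_length(res$fitness_history, 15)
  expect_true(all(diff(res$fitness_history) >= -1e-12))  # elitism_copy
  expect_equal(res$best$fitness, max(res$fitness_history))
  res2 <- ga_evolve(tab, "target", cfg)
  expect_identical(res$best, res2$best)
  expect_identical(res$fitness_history, res2$fitness_history)
  # early stop cuts the budget once fitness stalls
  cfg_es <- ga_config(population_size = 30, max_features = 5, generations = 100,
                      early_stop = TRUE, stall_generations = 5, seed = 11)
  res3 <- ga_evolve(tab, "target", cfg_es)
  expect_lte(res3$generations_run, 100)
  expect_error(ga_evolve(make_table(vals, y), "target", cfg), "standardized")
})
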