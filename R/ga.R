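#' Genetic-algorithm configuration
#'
#' Evolution parameters of the feature-subset GA. The defaults follow
#' the reference protocol: a population of 1,000 subsets of at most 15
#' features, the top 2% mated, shared features inherited, disputed
#' features inherited with a 50% chance, obligate mutation, and 200
#' generations. Mutation rates and the elite pairing scheme are not
#' fixed by that protocol; the defaults add on average about two
#' features per mutated individual at P around 1,200 and delete 5% of
#' selected features.
#'
#' @param population_size Number of individuals per generation.
#' @param max_features Maximum subset size.
#' @param elite_fraction Fraction of the population mated each
#'   generation (top of the fitness ranking).
#' @param generations Generation budget.
#' @param p_inherit_single_parent Probability that a feature held by
#'   exactly one parent is passed to the child.
#' @param p_add Per-absent-feature mutation add probability.
#' @param p_delete Per-selected-feature mutation delete probability.
#' @param elitism_copy Copy the elite unmutated into the next
#'   generation. Deviates from obligate mutation of every individual,
#'   but makes the best fitness non-decreasing; set `FALSE` for strictly
#'   obligate mutation.
#' @param child_fraction Fraction of the population produced by mating
#'   elite pairs; the remainder (after elites, if copied) is refilled
#'   with fresh random individuals.
#' @param early_stop If `TRUE`, stop once the best fitness has not
#'   improved by more than `stall_tol` for `stall_generations`
#'   generations.
#' @param stall_generations,stall_tol Early-stop window and tolerance.
#' @param seed Integer seed for the evolution.
#' @return Object of class `acg_ga_config`.
#' @export
ga_config <- function(population_size = 1000, max_features = 15,
                      elite_fraction = 0.02, generations = 200,
                      p_inherit_single_parent = 0.5,
                      p_add = 0.002, p_delete = 0.05,
                      elitism_copy = TRUE, child_fraction = 0.5,
                      early_stop = FALSE, stall_generations = 30,
                      stall_tol = 1e-4, seed = 1L) {
  if (population_size < 2) stopf("population_size must be >= 2")
  if (elite_fraction <= 0 || elite_fraction >= 1) stopf("elite_fraction must be in (0, 1)")
  probs <- c(p_inherit_single_parent, p_add, p_delete)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must be in [0, 1]")
  if (max_features < 1) stopf("max_features must be >= 1")
  if (child_fraction < 0 || child_fraction + elite_fraction > 1) {
    stopf("child_fraction must be in [0, 1 - elite_fraction]")
  }
  structure(as.list(environment())[c(
    "population_size", "max_features", "elite_fraction", "generations",
    "p_inherit_single_parent", "p_add", "p_delete", "elitism_copy",
    "child_fraction", "early_stop", "stall_generations", "stall_tol", "seed")],
    class = "acg_ga_config")
}

new_individual <- function(features) {
  list(features = as.integer(sort(features)), fitness = NA_real_)
}

#' Initialise a GA population
#'
#' `population_size` individuals, each a uniformly drawn feature subset
#' of size Uniform{1..max_features}. Consumes the current RNG stream.
#'
#' @param config [ga_config()].
#' @param n_features Number of columns of the feature table.
#' @return List of individuals (`features` index vector, `fitness`).
#' @export
init_population <- function(config, n_features) {
  if (n_features < 1) stopf("n_features must be >= 1")
  if (n_features < config$max_features) {
    stopf("n_features (%d) must be >= max_features (%d)", n_features, config$max_features)
  }
  sizes <- sample.int(config$max_features, config$population_size, replace = TRUE)
  lapply(sizes, function(k) new_individual(sample.int(n_features, k)))
}

# PC1 scores of the selected standardized submatrix (zero-mean columns);
# returns NULL when the submatrix has no variance
pc1_scores_matrix <- function(values, features) {
  x <- values[, features, drop = FALSE]
  cm <- colMeans(x)
  if (any(abs(cm) > 1e-8)) x <- sweep(x, 2, cm, "-")
  sv <- svd(x, nu = 1, nv = 0)
  if (sv$d[1] <= 1e-12) return(NULL)
  as.numeric(sv$u[, 1]) * sv$d[1]
}

#' PC1 scores of a feature subset
#'
#' First-principal-component scores of the selected columns of the
#' standardized feature table: the per-row values of the single linear
#' combination of the selected features that explains maximal variance.
#' These are the "trained components" plotted against clinical scores.
#'
#' @param individual An individual (list with `features`) or an integer
#'   vector of feature indices / character vector of feature names.
#' @param table A [standardize_features()] feature table.
#' @return Numeric vector of length `nrow(table$values)`, zero mean; the
#'   all-zero vector for a subset with no variance.
#' @export
pc1_scores <- function(individual, table) {
  stopifnot(inherits(table, "acg_feature_table"))
  feats <- if (is.list(individual)) individual$features else individual
  if (is.character(feats)) feats <- match(feats, table$feature_names)
  if (length(feats) < 1 || anyNA(feats)) stopf("invalid feature subset")
  s <- pc1_scores_matrix(table$values, feats)
  if (is.null(s)) rep(0, nrow(table$values)) else s
}

#' GA fitness: |Pearson r| between subset PC1 and a clinical target
#'
#' The first principal component of the selected standardized submatrix
#' is correlated with the target clinical parameter; the absolute value
#' of the Pearson correlation is the fitness (PC1 sign ambiguity is
#' irrelevant by construction). A zero-variance submatrix scores 0.
#'
#' @param individual See [pc1_scores()].
#' @param table Standardized [build_feature_table()] table.
#' @param target Numeric vector aligned with the table rows, or the name
#'   of a column of `table$targets`.
#' @return Fitness in \[0, 1\].
#' @export
ga_fitness <- function(individual, table, target) {
  target <- resolve_target(table, target)
  if (stats::sd(target) == 0) stopf("target has zero variance")
  feats <- if (is.list(individual)) individual$features else as.integer(individual)
  s <- pc1_scores_matrix(table$values, feats)
  if (is.null(s)) return(0)
  r <- safe_cor(s, target)
  abs(r)
}

resolve_target <- function(table, target) {
  if (is.character(target) && length(target) == 1) {
    if (!target %in% names(table$targets)) stopf("unknown target '%s'", target)
    target <- table$targets[[target]]
  }
  target <- as.numeric(target)
  if (length(target) != nrow(table$values)) stopf("target not aligned with table rows")
  target
}

#' Crossover of two feature subsets
#'
#' Shared features always pass to the child; features held by exactly
#' one parent pass independently with probability
#' `p_inherit_single_parent` (default 50%). An empty child is repaired
#' by adding one uniformly drawn parent feature. Consumes the RNG
#' stream.
#'
#' @param a,b Parent individuals.
#' @param config [ga_config()].
#' @return Child individual (fitness unset). The size cap is enforced by
#'   [ga_mutate()], which is obligate for children during evolution.
#' @export
ga_crossover <- function(a, b, config = ga_config()) {
  fa <- a$features; fb <- b$features
  common <- intersect(fa, fb)
  single <- setdiff(union(fa, fb), common)
  keep <- single[stats::runif(length(single)) < config$p_inherit_single_parent]
  child <- c(common, keep)
  if (length(child) == 0) child <- sample(union(fa, fb), 1)
  new_individual(child)
}

#' Mutate a feature subset
#'
#' Each absent feature is added with probability `p_add` and each
#' selected feature deleted with probability `p_delete` (both relative
#' to the incoming subset). Surplus features beyond `max_features` are
#' deleted uniformly at random; an empty result is repaired with one
#' uniform feature. Consumes the RNG stream.
#'
#' @param individual The individual to mutate.
#' @param config [ga_config()].
#' @param n_features Total number of features.
#' @return Mutated individual with `1 <= size <= max_features`.
#' @export
ga_mutate <- function(individual, config, n_features) {
  present <- individual$features
  absent <- setdiff(seq_len(n_features), present)
  n_add <- stats::rbinom(1, length(absent), config$p_add)
  added <- if (n_add > 0) sample(absent, n_add) else integer(0)
  kept <- if (length(present) > 0) {
    present[stats::runif(length(present)) >= config$p_delete]
  } else integer(0)
  out <- c(kept, added)
  if (length(out) > config$max_features) out <- sample(out, config$max_features)
  if (length(out) == 0) out <- sample.int(n_features, 1)
  new_individual(out)
}

#' Evolve feature subsets against a clinical target
#'
#' Runs the genetic algorithm: evaluate fitness, mate random pairs of
#' the elite (top `elite_fraction`), refill the remainder of the
#' population with fresh random individuals, mutate every child (elite
#' copies are exempt iff `elitism_copy`), for `generations` generations.
#'
#' @param table Standardized [build_feature_table()] table.
#' @param target Clinical target; see [ga_fitness()].
#' @param config [ga_config()] (its `seed` drives all randomness).
#' @return Object of class `acg_ga_result`: `best` individual (with
#'   `feature_names`), `fitness_history` (per-generation best),
#'   `generations_run`, `seed`, `config`, `target`.
#' @export
ga_evolve <- function(table, target, config = ga_config()) {
  stopifnot(inherits(table, "acg_feature_table"), inherits(config, "acg_ga_config"))
  if (!isTRUE(table$standardized)) {
    stopf("table must be standardized (see standardize_features)")
  }
  target_name <- if (is.character(target)) target else NA_character_
  tvec <- resolve_target(table, target)
  if (stats::sd(tvec) == 0) stopf("target has zero variance")
  n_features <- ncol(table$values)

  set.seed(as.integer(config$seed))
  pop <- init_population(config, n_features)
  n_elite <- max(2L, as.integer(round(config$population_size * config$elite_fraction)))
  n_children <- as.integer(round(config$population_size * config$child_fraction))

  best <- NULL
  best_fit <- -Inf
  history <- numeric(0)
  last_improvement <- 0L
  gens_run <- 0L

  for (gen in seq_len(config$generations)) {
    fits <- vapply(pop, function(ind) ga_fitness(ind, table, tvec), numeric(1))
    gen_best <- max(fits)
    history <- c(history, gen_best)
    if (gen_best > best_fit + config$stall_tol) last_improvement <- gen
    if (gen_best > best_fit) {
      best_fit <- gen_best
      best <- pop[[which.max(fits)]]
      best$fitness <- gen_best
    }
    gens_run <- gen
    if (config$early_stop && gen - last_improvement >= config$stall_generations) break
    if (gen == config$generations) break

    ord <- order(fits, decreasing = TRUE)
    elite <- pop[ord[seq_len(min(n_elite, length(pop)))]]
    children <- lapply(seq_len(n_children), function(i) {
      pair <- sample.int(length(elite), 2, replace = TRUE)
      ga_mutate(ga_crossover(elite[[pair[1]]], elite[[pair[2]]], config),
                config, n_features)
    })
    n_fresh <- config$population_size - n_children -
      if (config$elitism_copy) length(elite) else 0L
    fresh <- if (n_fresh > 0) {
      sizes <- sample.int(config$max_features, n_fresh, replace = TRUE)
      lapply(sizes, function(k) new_individual(sample.int(n_features, k)))
    } else list()
    pop <- c(if (config$elitism_copy) elite else list(), children, fresh)
  }

  best$feature_names <- table$feature_names[best$features]
  structure(list(best = best, fitness_history = history,
                 generations_run = gens_run, seed = config$seed,
                 config = config, target = target_name),
            class = "acg_ga_result")
}

#' @export
print.acg_ga_result <- function(x, ...) {
  cat(sprintf("ACG GA result%s: best fitness %.4f with %d features after %d generations\n",
              if (!is.na(x$target)) sprintf(" (target %s)", x$target) else "",
              x$best$fitness, length(x$best$features), x$generations_run))
  cat("  features:", paste(x$best$feature_names, collapse = ", "), "\n")
  invisible(x)
}
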