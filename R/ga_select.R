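# Elitist genetic algorithm over binary descriptor subsets, with
# leave-one-out KNN fitness (the number of correctly classified molecules).
#
# Published hyperparameters: population 5000, top 1000 pass unaltered, the
# remaining 4000 come from single-point crossover of elite pairs followed by
# per-bit point mutation with probability 1e-3. Elite ranking ties are broken
# by subset cardinality (parsimony) and then lexicographic bit order; parent
# sampling is uniform with replacement from the elite, self-pairing allowed.
# Termination (unstated in the original description) is max_generations or a
# perfect, unchanged best subset for stall_generations.

.genome_key <- function(genome) rawToChar(as.raw(genome + 48L))

#' Genetic algorithm configuration
#'
#' @param population_size genomes per generation (default 5000).
#' @param elite_size genomes copied unaltered each generation (default 1000).
#' @param offspring_size genomes created by crossover + mutation (default
#'   4000); must be even and `elite_size + offspring_size ==
#'   population_size`.
#' @param mutation_rate per-bit flip probability (default 1e-3).
#' @param k neighbors for the KNN fitness (default 1).
#' @param max_generations hard generation cap (default 200).
#' @param stall_generations stop once the best subset is perfect and
#'   unchanged this many consecutive generations (default 20).
#' @param random_init_density per-bit density of the random part of the
#'   initial population (default 0.5).
#' @param seed integer seed; the whole run is reproducible from it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 5000L, elite_size = 1000L,
                      offspring_size = 4000L, mutation_rate = 1e-3,
                      k = 1L, max_generations = 200L,
                      stall_generations = 20L, random_init_density = 0.5,
                      seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              elite_size = as.integer(elite_size),
              offspring_size = as.integer(offspring_size),
              mutation_rate = mutation_rate, k = as.integer(k),
              max_generations = as.integer(max_generations),
              stall_generations = as.integer(stall_generations),
              random_init_density = random_init_density,
              seed = as.integer(seed))
  if (cfg$population_size < 2L)
    stop("config error: population_size must be >= 2", call. = FALSE)
  if (cfg$elite_size + cfg$offspring_size != cfg$population_size)
    stop("config error: elite_size + offspring_size must equal population_size",
         call. = FALSE)
  if (cfg$offspring_size %% 2L != 0L)
    stop("config error: offspring_size must be even", call. = FALSE)
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stop("config error: mutation_rate must be in [0, 1]", call. = FALSE)
  if (cfg$random_init_density <= 0 || cfg$random_init_density >= 1)
    stop("config error: random_init_density must be in (0, 1)", call. = FALSE)
  structure(cfg, class = "ga_config")
}

#' Initial genome population
#'
#' Genome 1 selects every descriptor; genomes 2..(n_descriptors + 1) are the
#' singletons, one per descriptor; the remainder are random with per-bit
#' density `random_init_density`. Truncated to `population_size` if the
#' deterministic part alone exceeds it. Uses the current RNG state; seed via
#' [run_ga()] or `withr::with_seed()` for reproducibility.
#'
#' @param n_descriptors genome length (>= 1).
#' @param config a [ga_config()].
#' @return List of integer 0/1 vectors of length `population_size`.
#' @export
init_population <- function(n_descriptors, config) {
  stopifnot(inherits(config, "ga_config"), n_descriptors >= 1L)
  p <- as.integer(n_descriptors)
  pop <- vector("list", config$population_size)
  pop[[1L]] <- rep(1L, p)
  i <- 1L
  while (i <= p && i + 1L <= config$population_size) {
    g <- rep(0L, p); g[i] <- 1L
    pop[[i + 1L]] <- g
    i <- i + 1L
  }
  filled <- min(p + 1L, config$population_size)
  for (j in seq_len(config$population_size - filled))
    pop[[filled + j]] <-
      as.integer(stats::runif(p) < config$random_init_density)
  pop
}

#' Single-point crossover
#'
#' Exchanges the tails of two equal-length genomes after position `cut`,
#' producing two children.
#'
#' @param parent_a,parent_b integer 0/1 vectors of equal length.
#' @param cut crossover point, `1 <= cut <= length - 1`; child 1 takes
#'   `parent_a[1:cut]` then `parent_b[(cut+1):L]`, child 2 the converse.
#' @return List of the two child genomes.
#' @export
ga_crossover <- function(parent_a, parent_b, cut) {
  L <- length(parent_a)
  if (length(parent_b) != L)
    stop("parent genome lengths differ", call. = FALSE)
  if (cut < 1L || cut > L - 1L)
    stop("cut must be between 1 and length - 1", call. = FALSE)
  head_idx <- seq_len(cut); tail_idx <- (cut + 1L):L
  list(c(parent_a[head_idx], parent_b[tail_idx]),
       c(parent_b[head_idx], parent_a[tail_idx]))
}

#' Point mutation
#'
#' Flips each bit independently with probability `rate` (a switch of the bit
#' to the other value). Uses the current RNG state.
#'
#' @param genome integer 0/1 vector.
#' @param rate per-bit flip probability in `[0, 1]`.
#' @return The mutated genome.
#' @export
ga_mutate <- function(genome, rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  flip <- stats::runif(length(genome)) < rate
  genome[flip] <- 1L - genome[flip]
  genome
}

.rank_population <- function(population, fitnesses) {
  card <- vapply(population, sum, numeric(1))
  keys <- vapply(population, .genome_key, character(1))
  order(-fitnesses, card, keys)
}

#' One generation of the elitist GA
#'
#' The top `elite_size` genomes (fitness descending, then cardinality
#' ascending, then lexicographic bits) pass unaltered; `offspring_size / 2`
#' parent pairs are drawn uniformly with replacement from the elite, crossed
#' at a uniform random cut, and both children are mutated.
#'
#' @param population list of genomes.
#' @param fitnesses numeric vector, one fitness per genome.
#' @param config a [ga_config()].
#' @return The next population (same size).
#' @export
step_generation <- function(population, fitnesses, config) {
  stopifnot(inherits(config, "ga_config"))
  if (length(population) != length(fitnesses))
    stop("population/fitness length mismatch", call. = FALSE)
  ord <- .rank_population(population, fitnesses)
  elite <- population[ord[seq_len(min(config$elite_size,
                                      length(population)))]]
  L <- length(population[[1L]])
  n_pairs <- config$offspring_size %/% 2L
  offspring <- vector("list", config$offspring_size)
  for (pair in seq_len(n_pairs)) {
    idx <- sample.int(length(elite), 2L, replace = TRUE)
    cut <- if (L > 1L) sample.int(L - 1L, 1L) else 1L
    children <- if (L > 1L)
      ga_crossover(elite[[idx[1L]]], elite[[idx[2L]]], cut)
    else list(elite[[idx[1L]]], elite[[idx[2L]]])
    offspring[[2L * pair - 1L]] <- ga_mutate(children[[1L]],
                                             config$mutation_rate)
    offspring[[2L * pair]] <- ga_mutate(children[[2L]],
                                        config$mutation_rate)
  }
  c(elite, offspring)
}

#' Run the genetic descriptor-subset search
#'
#' Iterates [step_generation()] with [loo_fitness()] (number of correctly
#' classified molecules under leave-one-out KNN) as the fitness, until
#' `max_generations` or until the best subset classifies every molecule
#' correctly and has been unchanged for `stall_generations` generations.
#' Fitness values are cached by genome, since elitist populations re-evaluate
#' many duplicates. Fully reproducible from `config$seed`.
#'
#' @param matrix a labelled [descriptor_matrix()] with both classes present.
#' @param config a [ga_config()].
#' @param scale standardize the matrix before distance computation
#'   (default `TRUE`; `FALSE` reproduces the raw-value reading).
#' @return A `ga_result` list: `best_subset` (integer 0/1 vector, named by
#'   descriptor), `best_fitness`, `history` (data frame of per-generation
#'   best and mean fitness), `generations_run`, `seed`.
#' @examples
#' \donttest{
#' dm <- load_descriptor_table()
#' res <- run_ga(dm, ga_config(population_size = 500L, elite_size = 100L,
#'                             offspring_size = 400L, seed = 1L,
#'                             max_generations = 30L))
#' res$best_fitness
#' }
#' @export
run_ga <- function(matrix, config = ga_config(), scale = TRUE) {
  stopifnot(inherits(config, "ga_config"))
  if (!inherits(matrix, "descriptor_matrix"))
    stop("`matrix` must be a descriptor_matrix", call. = FALSE)
  if (is.null(matrix$labels) || length(unique(matrix$labels)) < 2L)
    stop("labelled matrix with both classes required", call. = FALSE)
  work <- if (scale) standardize(matrix) else matrix
  p <- ncol(work$values)
  n <- nrow(work$values)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(genome) {
    key <- .genome_key(genome)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- loo_fitness(work, subset = genome, k = config$k)$n_correct
    cache[[key]] <- val
    val
  }
  withr::with_seed(config$seed, {
    pop <- init_population(p, config)
    hist_best <- hist_mean <- numeric(0)
    stall <- 0L
    prev_key <- NULL
    best_genome <- NULL
    best_fitness <- -Inf
    gens <- 0L
    for (gen in seq_len(config$max_generations)) {
      fit <- vapply(pop, fitness_of, numeric(1))
      ord <- .rank_population(pop, fit)
      top <- pop[[ord[1L]]]
      top_key <- .genome_key(top)
      gens <- gen
      hist_best <- c(hist_best, fit[ord[1L]])
      hist_mean <- c(hist_mean, mean(fit))
      best_genome <- top
      best_fitness <- fit[ord[1L]]
      if (best_fitness == n && identical(top_key, prev_key))
        stall <- stall + 1L
      else stall <- 0L
      prev_key <- top_key
      if (best_fitness == n && stall >= config$stall_generations) break
      if (gen < config$max_generations)
        pop <- step_generation(pop, fit, config)
    }
  })
  names(best_genome) <- descriptor_names(work)
  structure(list(
    best_subset = best_genome,
    best_fitness = as.integer(best_fitness),
    history = data.frame(generation = seq_len(gens), best = hist_best,
                         mean = hist_mean),
    generations_run = gens,
    seed = config$seed
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result: fitness %d after %d generation(s); %d descriptor(s) selected>\n",
              x$best_fitness, x$generations_run, sum(x$best_subset)))
  sel <- names(x$best_subset)[x$best_subset == 1L]
  if (length(sel) <= 20L) cat("selected:", paste(sel, collapse = ", "), "\n")
  invisible(x)
}
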