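#' Genetic-algorithm parameters for subset optimization
#'
#' Hyperparameters for the fixed-size-subset genetic algorithm used by
#' [select_unrelated()]: population size, tournament selection size,
#' per-individual swap-mutation probability, and the generation budget
#' with an early-stopping stall window.
#'
#' @param pop_size Number of candidate subsets per generation (default 50).
#' @param tournament Tournament size for parent selection (default 3).
#' @param mutation_rate Probability that an offspring has one member
#'   swapped for a non-member (default 0.1).
#' @param max_generations Generation budget (default 200).
#' @param stall_generations Stop early after this many generations without
#'   improvement (default 30).
#' @return A validated list of class `ga_params`.
#' @export
ga_params <- function(pop_size = 50, tournament = 3, mutation_rate = 0.1,
                      max_generations = 200, stall_generations = 30) {
  if (pop_size < 2) abort("ga pop_size must be >= 2")
  if (tournament < 1 || tournament > pop_size) abort("ga tournament must be in [1, pop_size]")
  if (mutation_rate < 0 || mutation_rate > 1) abort("ga mutation_rate must be in [0, 1]")
  if (max_generations < 1) abort("ga max_generations must be >= 1")
  structure(list(pop_size = as.integer(pop_size), tournament = as.integer(tournament),
                 mutation_rate = mutation_rate,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations)),
            class = "ga_params")
}

# Minimize fitness_fn over size-k subsets of 1..n by a steady elitist GA:
# tournament selection, membership-uniform crossover repaired to size k,
# swap mutation. Returns best subset (sorted), its fitness, and a history.
ga_subset_min <- function(fitness_fn, n, k, params = ga_params()) {
  stopifnot(inherits(params, "ga_params"), k >= 1, k <= n)
  if (k == n) {
    return(list(best = seq_len(n), fitness = fitness_fn(seq_len(n)),
                generations = 0L, history = numeric(0)))
  }
  pop <- replicate(params$pop_size, sort(sample.int(n, k)), simplify = FALSE)
  fit <- vapply(pop, fitness_fn, numeric(1))
  best_i <- which.min(fit)
  best <- pop[[best_i]]
  best_fit <- fit[best_i]
  history <- numeric(0)
  stall <- 0L
  gens <- 0L

  tournament_pick <- function() {
    cand <- sample.int(params$pop_size, params$tournament)
    cand[which.min(fit[cand])]
  }
  crossover <- function(p1, p2) {
    common <- intersect(p1, p2)
    rest <- setdiff(union(p1, p2), common)
    need <- k - length(common)
    child <- c(common, if (need > 0) rest[sample.int(length(rest), need)] else integer(0))
    sort(child)
  }
  mutate <- function(x) {
    if (runif(1) < params$mutation_rate) {
      out <- setdiff(seq_len(n), x)
      x[sample.int(k, 1)] <- out[sample.int(length(out), 1)]
      x <- sort(x)
    }
    x
  }

  for (g in seq_len(params$max_generations)) {
    gens <- g
    newpop <- vector("list", params$pop_size)
    newpop[[1]] <- best  # elitism
    for (j in 2:params$pop_size) {
      child <- crossover(pop[[tournament_pick()]], pop[[tournament_pick()]])
      newpop[[j]] <- mutate(child)
    }
    pop <- newpop
    fit <- vapply(pop, fitness_fn, numeric(1))
    gen_best <- which.min(fit)
    if (fit[gen_best] < best_fit - 1e-15) {
      best_fit <- fit[gen_best]
      best <- pop[[gen_best]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    history <- c(history, best_fit)
    if (stall >= params$stall_generations) break
  }
  list(best = best, fitness = best_fit, generations = gens, history = history)
}
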