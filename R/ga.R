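#' Genetic-algorithm configuration
#'
#' Hyperparameters of the real-coded generational GA used by [fit_sir()].
#' The gene vector is `theta = (alpha, beta, mu, S0, K)`. Defaults: a
#' population of 100 evolved for 500 generations, crossover probability 0.8,
#' per-gene mutation probability 0.1, Baker linear ranking at maximum
#' selective pressure 2, and one elite individual carried unchanged — a
#' conventional configuration for low-dimensional real-coded search.
#'
#' `bounds` defines the feasible set: a named list of `c(lower, upper)` pairs
#' per gene. When `NULL`, [fit_sir()] derives data-scaled bounds (see its
#' documentation).
#'
#' @param population_size Number of individuals (`>= 2`).
#' @param generations Number of generations (`>= 1`).
#' @param crossover_prob Probability a parent pair is recombined.
#' @param mutation_prob Per-gene mutation probability.
#' @param selective_pressure Linear-ranking pressure in `[1, 2]`.
#' @param elitism_count Number of best individuals copied unchanged.
#' @param bounds Optional named list of per-gene `c(lower, upper)` pairs.
#' @param seed Integer seed making the fit reproducible.
#' @return An object of class `ga_config` (a named list).
#' @export
ga_config <- function(population_size = 100, generations = 500,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      selective_pressure = 2, elitism_count = 1,
                      bounds = NULL, seed = 20260101) {
  if (population_size < 2) abort("`population_size` must be at least 2.")
  if (generations < 1) abort("`generations` must be at least 1.")
  for (p in c(crossover_prob, mutation_prob)) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1].")
  }
  if (selective_pressure < 1 || selective_pressure > 2) {
    abort("`selective_pressure` must lie in [1, 2].")
  }
  if (elitism_count < 0) abort("`elitism_count` must be non-negative.")
  if (!is.null(bounds)) check_bounds(bounds)
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         selective_pressure = selective_pressure,
         elitism_count = as.integer(elitism_count),
         bounds = bounds, seed = as.integer(seed)),
    class = "ga_config"
  )
}

check_bounds <- function(bounds) {
  ok <- vapply(bounds, function(b) {
    length(b) == 2L && all(is.finite(b)) && b[1] < b[2]
  }, logical(1))
  if (!all(ok)) {
    abort(sprintf("invalid bounds for gene(s): %s (need finite lower < upper).",
                  paste(names(bounds)[!ok], collapse = ", ")))
  }
  invisible(bounds)
}

#' Baker linear-ranking fitness
#'
#' Assigns selection fitness from objective rank rather than raw objective
#' value: with `N` individuals ranked so the lowest objective gets rank `N`,
#' fitness at rank `r` is `2 - SP + 2 (SP - 1)(r - 1)/(N - 1)`, where `SP`
#' is the selective pressure in `[1, 2]`. The best individual receives `SP`
#' and the worst `2 - SP`; mean fitness is always 1, so the fitness vector
#' sums to `N`. Ties are broken by stable original order.
#'
#' @param objectives Numeric vector of objective values (lower is better).
#' @param selective_pressure Real in `[1, 2]`.
#' @return Numeric fitness vector aligned with `objectives`.
#' @examples
#' rank_fitness(c(5, 1, 3), selective_pressure = 2)
#' @export
rank_fitness <- function(objectives, selective_pressure = 2) {
  n <- length(objectives)
  if (n < 2) abort("linear ranking needs at least 2 individuals.")
  if (selective_pressure < 1 || selective_pressure > 2) {
    abort("`selective_pressure` must lie in [1, 2].")
  }
  ord <- order(objectives)              # ascending; stable for ties
  rank <- integer(n)
  rank[ord] <- seq(n, 1)                # smallest objective gets rank n (best)
  sp <- selective_pressure
  2 - sp + 2 * (sp - 1) * (rank - 1) / (n - 1)
}

#' Roulette-wheel selection
#'
#' Samples individuals with replacement with probability proportional to
#' fitness.
#'
#' @param fitness Non-negative fitness vector with at least one positive entry.
#' @param count Number of indices to draw.
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(fitness, count) {
  if (any(fitness < 0)) abort("fitness values must be non-negative.")
  if (all(fitness == 0)) abort("all fitness values are zero: wheel undefined.")
  sample.int(length(fitness), size = count, replace = TRUE, prob = fitness)
}

#' Single-point crossover
#'
#' Draws a cut point uniformly from the `L - 1` internal gene boundaries and
#' swaps the gene tails of the two parents; gene values themselves are never
#' altered, so the multiset of genes across the pair is conserved.
#'
#' @param parent_a,parent_b Numeric gene vectors of equal length `L >= 2`.
#' @return A list with elements `child_a` and `child_b`.
#' @export
single_point_crossover <- function(parent_a, parent_b) {
  L <- length(parent_a)
  if (L < 2 || length(parent_b) != L) {
    abort("parents must be equal-length gene vectors with at least 2 genes.")
  }
  cut <- sample.int(L - 1L, 1L)
  list(child_a = c(parent_a[seq_len(cut)], parent_b[(cut + 1L):L]),
       child_b = c(parent_b[seq_len(cut)], parent_a[(cut + 1L):L]))
}

#' Real-value mutation (Muehlenbein scheme)
#'
#' Perturbs a real gene by `s * r * a`, where `s` is a random sign, the
#' mutation range `r` is 10% of the gene's bound width, and `a = 2^(-u k)`
#' with `u` uniform on `[0, 1]` and precision `k = 16`. Steps are therefore
#' bounded by `r` but concentrate near zero, giving fine local search with
#' occasional larger moves. The result is clipped into the bounds.
#'
#' @param gene Current gene value, inside `bounds`.
#' @param bounds Numeric `c(lower, upper)` with `lower < upper`.
#' @param range_frac Mutation range as a fraction of the bound width.
#' @param precision The exponent constant `k`.
#' @return The mutated gene value.
#' @export
real_value_mutation <- function(gene, bounds, range_frac = 0.1,
                                precision = 16) {
  lower <- bounds[1]; upper <- bounds[2]
  if (lower >= upper) abort("`bounds` must satisfy lower < upper.")
  r <- range_frac * (upper - lower)
  s <- if (runif(1) < 0.5) -1 else 1
  a <- 2^(-runif(1) * precision)
  min(max(gene + s * r * a, lower), upper)
}
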