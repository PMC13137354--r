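# Pufferfish optimization over a discrete candidate set (patch sizes):
# a small population metaheuristic whose members move toward the best-known
# position (exploration, coefficient beta) and away from the worst-fitness
# "predator" position (evasion, coefficient alpha), with continuous
# positions snapped to the nearest valid candidate for evaluation.

#' Pufferfish-optimizer configuration
#'
#' @param candidate_patch_sizes Discrete candidate set (default
#'   `c(4, 8, 16, 32)`); all must divide the image side they will be used
#'   on.
#' @param population_size Population size (>= 2, default 10).
#' @param n_iterations Iterations (default 20).
#' @param alpha Evasion coefficient in (0, 1].
#' @param beta Exploration coefficient in (0, 1].
#' @param seed Integer seed.
#' @return A `poa_config` object.
#' @export
poa_config <- function(candidate_patch_sizes = c(4L, 8L, 16L, 32L),
                       population_size = 10L, n_iterations = 20L,
                       alpha = 0.5, beta = 0.8, seed = 0L) {
  if (length(candidate_patch_sizes) == 0L) stop("empty candidate set")
  if (population_size < 2L) stop("population_size must be >= 2")
  stopifnot(alpha > 0, alpha <= 1, beta > 0, beta <= 1)
  structure(list(candidates = sort(unique(as.numeric(candidate_patch_sizes))),
                 population_size = as.integer(population_size),
                 n_iterations = as.integer(n_iterations),
                 alpha = alpha, beta = beta, seed = as.integer(seed)),
            class = "poa_config")
}

#' Pufferfish optimization over a discrete candidate set
#'
#' Lower fitness is better. The initial population cycles through the
#' candidate set (every candidate is represented whenever the population is
#' at least as large), and the best-ever candidate is retained (elitism),
#' so the best-fitness history is non-increasing and on small candidate
#' spaces the result matches exhaustive search.
#'
#' @param fitness Function `candidate -> numeric` (lower is better).
#' @param config A [poa_config()].
#' @return List with `best_candidate`, `best_fitness`, and `history`
#'   (best-ever fitness per iteration).
#' @export
poa_optimize <- function(fitness, config = poa_config()) {
  cands <- config$candidates
  if (length(cands) == 0L) stop("empty candidate set")
  snap <- function(x) cands[max.col(-abs(outer(x, cands, "-")),
                                    ties.method = "first")]
  if (length(cands) == 1L) {
    f <- fitness(cands)
    return(list(best_candidate = cands, best_fitness = f, history = f))
  }
  with_seed(substream_seed(config$seed, "poa"), {
    n <- config$population_size
    x <- rep_len(cands, n)                       # cycle: full coverage
    fit <- vapply(snap(x), fitness, 0)
    best_i <- which.min(fit)
    best_x <- snap(x)[best_i]; best_f <- fit[best_i]
    history <- numeric(config$n_iterations)
    for (it in seq_len(config$n_iterations)) {
      worst_x <- x[which.max(fit)]
      r1 <- stats::runif(n); r2 <- stats::runif(n)
      x <- x + config$beta * r1 * (best_x - x) -
        config$alpha * r2 * (worst_x - x)
      x <- clamp(x, min(cands), max(cands))
      xc <- snap(x)
      fit <- vapply(xc, fitness, 0)
      i <- which.min(fit)
      if (fit[i] < best_f) { best_f <- fit[i]; best_x <- xc[i] }
      history[it] <- best_f
    }
    list(best_candidate = best_x, best_fitness = best_f, history = history)
  })
}
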