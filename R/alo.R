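# Binary Ant Lion Optimizer.
#
# The continuous ALO's random-walk machinery does not preserve a binary
# encoding, so positions here are binary masks over the exchange set:
# random walks are replaced by single-bit flip mutations, the elite and
# a roulette-selected ant lion each contribute a mutated copy, and the
# ant's new position takes each bit from one of the two copies with
# equal probability.  An ant that outscores its trap owner replaces it
# (catch and rebuild), and the best ant lion ever seen is kept as the
# elite.

#' ALO solver parameters
#'
#' @param n_ants,n_antlions colony sizes (default 200 each; the two
#'   colonies share a single published population-size setting).
#' @param iterations number of generations (default 200).
#' @return list of class `alo_params`.
#' @export
alo_params <- function(n_ants = 200, n_antlions = 200, iterations = 200) {
  stopifnot(n_ants >= 1, n_antlions >= 1, iterations >= 1)
  structure(list(n_ants = as.integer(n_ants),
                 n_antlions = as.integer(n_antlions),
                 iterations = as.integer(iterations)),
            class = "alo_params")
}

#' Great-value-priority binarization
#'
#' Maps a continuous vector to a binary one through its descending rank
#' permutation P (ties broken towards the lower index): bit i is 1 when
#' `P[i] >= P[i + 1]`, and the last bit is 0.  Used to seed binary
#' populations from uniform random vectors, reflecting a priority-order
#' relation among dimensions.
#'
#' @param x numeric vector, length >= 1.
#' @return integer 0/1 vector of the same length.
#' @examples
#' gvp_binarize(c(3, 2, 1))  # 0 0 0
#' gvp_binarize(c(1, 2, 3))  # 1 1 0
#' @export
gvp_binarize <- function(x) {
  d <- length(x)
  if (d == 0) stop("x must be non-empty")
  P <- order(-x, seq_len(d))
  if (d == 1) return(0L)
  as.integer(c(P[-d] >= P[-1], FALSE))
}

#' Fitness-proportionate (roulette-wheel) selection
#'
#' Returns one index with probability proportional to the shifted
#' fitness `f - min(f) + eps`.  The shift accommodates the negative
#' fitness values produced by the infeasibility penalty; `eps` keeps the
#' worst individual selectable.
#'
#' @param fitness numeric vector.
#' @param n number of independent draws.
#' @param eps small positive shift, default `1e-9`.
#' @return integer index vector of length `n`.
#' @export
roulette_select <- function(fitness, n = 1, eps = 1e-9) {
  stopifnot(length(fitness) >= 1)
  s <- fitness - min(fitness) + eps
  sample.int(length(fitness), n, replace = TRUE, prob = s)
}

#' Single-bit flip mutation
#'
#' Flips one uniformly chosen dimension of a binary position (the binary
#' stand-in for a random walk step).
#'
#' @param position binary vector.
#' @param i dimension to flip; drawn uniformly when `NULL`.
#' @return mutated binary vector.
#' @export
flip_mutation <- function(position, i = NULL) {
  d <- length(position)
  stopifnot(d >= 1)
  if (is.null(i)) i <- sample.int(d, 1)
  position[i] <- 1L - position[i]
  position
}

#' Crossover of the two mutated guides
#'
#' Builds an ant's new position from the mutated roulette-selected ant
#' lion `RA` and the mutated elite `RE`: each bit is taken from `RE`
#' where the uniform draw is below 0.5, otherwise from `RA`.
#'
#' @param RA,RE binary vectors of equal length.
#' @param r optional vector of uniform draws (for testing); generated
#'   when `NULL`.
#' @return binary vector.
#' @export
ant_update <- function(RA, RE, r = NULL) {
  if (length(RA) != length(RE)) stop("RA and RE must have equal length")
  if (is.null(r)) r <- stats::runif(length(RA))
  ifelse(r < 0.5, RE, RA)
}

#' Catch and rebuild
#'
#' If the ant is strictly fitter than the ant lion whose trap caught it,
#' the ant lion takes over the ant's position (and fitness).
#'
#' @param state an `alo_state` from [initialize_population()].
#' @param ant_index,antlion_index 1-based indices.
#' @return the (possibly) updated state.
#' @export
catch_and_rebuild <- function(state, ant_index, antlion_index) {
  if (state$ant_fitness[ant_index] > state$antlion_fitness[antlion_index]) {
    state$antlions[antlion_index, ] <- state$ants[ant_index, ]
    state$antlion_fitness[antlion_index] <- state$ant_fitness[ant_index]
  }
  state
}

#' Initialize ALO populations
#'
#' Each ant and ant lion position is the great-value-priority
#' binarization of an independent uniform vector on \[0, 1\]^d.  All
#' fitness values are evaluated and the elite (best ant lion) recorded.
#'
#' @param M an `exchange_set` (defines the dimension d = |M|).
#' @param params an [alo_params()] list.
#' @param lambda penalty weight passed to [evaluate_selection()].
#' @return list of class `alo_state` with binary matrices `ants`,
#'   `antlions`, fitness vectors, `elite` position and `elite_fitness`.
#' @export
initialize_population <- function(M, params = alo_params(),
                                  lambda = default_lambda(M)) {
  d <- length(M$exchanges)
  stopifnot(d >= 1)
  usage <- exchange_usage(M)
  ants <- t(vapply(seq_len(params$n_ants),
                   function(i) gvp_binarize(stats::runif(d)), integer(d)))
  antlions <- t(vapply(seq_len(params$n_antlions),
                       function(i) gvp_binarize(stats::runif(d)), integer(d)))
  if (d == 1) { ants <- t(ants); antlions <- t(antlions) }
  ant_fitness <- batch_fitness(ants, usage, lambda, graded = TRUE)$fitness
  antlion_fitness <- batch_fitness(antlions, usage, lambda, graded = TRUE)$fitness
  best <- which.max(antlion_fitness)
  structure(list(ants = ants, antlions = antlions,
                 ant_fitness = ant_fitness,
                 antlion_fitness = antlion_fitness,
                 elite = antlions[best, ], elite_fitness = antlion_fitness[best],
                 usage = usage, lambda = lambda),
            class = "alo_state")
}

#' Run the binary Ant Lion Optimizer
#'
#' Per generation, every ant picks an ant lion by roulette selection on
#' the current ant-lion fitness, builds the two mutated guides (selected
#' ant lion and elite, one bit flipped each), takes each bit from one of
#' them at random, and is re-evaluated.  Ants then replace their trap
#' owners wherever strictly fitter, and the elite is updated when an ant
#' lion beats it.  The elite after the last generation is returned along
#' with its per-generation fitness trace.
#'
#' @param M an `exchange_set`.
#' @param params an [alo_params()] list.
#' @param lambda penalty weight (default 10 times the number of distinct
#'   nodes in `M`).
#' @param seed optional integer seed.
#' @return a `kpd_solution` with the elite selection and a
#'   non-decreasing `trace` of elite fitness per generation.
#' @export
alo_solve <- function(M, params = alo_params(), lambda = default_lambda(M),
                      seed = NULL) {
  stopifnot(inherits(M, "exchange_set"))
  if (!is.null(seed)) set.seed(seed)
  d <- length(M$exchanges)
  if (d == 0)
    return(new_kpd_solution(integer(), M, lambda, "alo", trace = numeric()))

  st <- initialize_population(M, params, lambda)
  usage <- st$usage
  antlions <- st$antlions
  alfit <- st$antlion_fitness
  elite <- st$elite
  elite_fit <- st$elite_fitness
  n_ants <- params$n_ants
  trace <- numeric(params$iterations)

  for (gen in seq_len(params$iterations)) {
    sel <- roulette_select(alfit, n_ants)
    # mutated guides: one random bit flipped per row
    RA <- antlions[sel, , drop = FALSE]
    flip <- cbind(seq_len(n_ants), sample.int(d, n_ants, replace = TRUE))
    RA[flip] <- 1L - RA[flip]
    RE <- matrix(elite, n_ants, d, byrow = TRUE)
    flip <- cbind(seq_len(n_ants), sample.int(d, n_ants, replace = TRUE))
    RE[flip] <- 1L - RE[flip]
    take_re <- matrix(stats::runif(n_ants * d), n_ants, d) < 0.5
    ants <- RA
    ants[take_re] <- RE[take_re]
    antfit <- batch_fitness(ants, usage, lambda, graded = TRUE)$fitness
    # catch and rebuild: an ant fitter than its trap owner replaces it
    for (i in seq_len(n_ants)) {
      j <- sel[i]
      if (antfit[i] > alfit[j]) {
        antlions[j, ] <- ants[i, ]
        alfit[j] <- antfit[i]
      }
    }
    best <- which.max(alfit)
    if (alfit[best] > elite_fit) {
      elite <- antlions[best, ]
      elite_fit <- alfit[best]
    }
    trace[gen] <- elite_fit
  }
  new_kpd_solution(elite, M, lambda, "alo", trace = trace, seed = seed)
}
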