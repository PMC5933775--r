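# Baseline solvers: an exact branch-and-bound for the weighted
# set-packing model (each node in at most one selected exchange) and a
# generational genetic algorithm sharing the penalized fitness.

#' Exact optimal clearing
#'
#' Maximizes total selected utility subject to every node appearing in
#' at most one selected exchange -- a maximum-weight independent set on
#' the exchange conflict graph, solved by depth-first branch and bound.
#' Exchanges are explored in descending-utility order and branches are
#' pruned when the incumbent cannot be beaten by the remaining utility,
#' so the search is exhaustive-equivalent but far cheaper than the
#' 2^|M| enumeration.
#'
#' @param M an `exchange_set`.
#' @param lambda penalty weight recorded on the returned solution (the
#'   exact solution is always feasible, so it only affects reporting).
#' @return a `kpd_solution` with `method = "exact"`.
#' @export
solve_exact <- function(M, lambda = default_lambda(M)) {
  stopifnot(inherits(M, "exchange_set"))
  d <- length(M$exchanges)
  if (d == 0) return(new_kpd_solution(integer(), M, lambda, "exact"))

  u <- exchange_utilities(M)
  ord <- order(-u, seq_len(d))
  uo <- u[ord]
  D <- exchange_usage(M)$D[, ord, drop = FALSE]
  conflict <- crossprod(D) > 0
  diag(conflict) <- FALSE

  # suffix sums bound the utility still reachable from position i
  suffix <- rev(cumsum(rev(uo)))
  best_val <- -Inf
  best_sel <- logical(d)
  cur_sel <- logical(d)

  rec <- function(i, cur, avail) {
    if (cur > best_val) {
      best_val <<- cur
      best_sel <<- cur_sel
    }
    while (i <= d && !avail[i]) i <- i + 1
    if (i > d) return()
    remaining <- sum(uo[avail & seq_len(d) >= i])
    if (cur + remaining <= best_val) return()
    # include exchange i
    cur_sel[i] <<- TRUE
    avail2 <- avail
    avail2[i] <- FALSE
    avail2[conflict[i, ]] <- FALSE
    rec(i + 1, cur + uo[i], avail2)
    cur_sel[i] <<- FALSE
    # exclude exchange i
    avail[i] <- FALSE
    rec(i + 1, cur, avail)
  }
  rec(1, 0, rep(TRUE, d))

  selection <- integer(d)
  selection[ord[best_sel]] <- 1L
  new_kpd_solution(selection, M, lambda, "exact")
}

#' GA solver parameters
#'
#' Published baseline settings: population 800, 100 generations,
#' crossover probability 0.8, mutation probability 0.2, roulette-wheel
#' parent selection.
#'
#' @param population,iterations population size and generation count.
#' @param crossover_prob,mutation_prob probabilities in \[0, 1\].
#' @param crossover `"single"` (single-point, default) or `"uniform"`.
#' @return list of class `ga_params`.
#' @export
ga_params <- function(population = 800, iterations = 100,
                      crossover_prob = 0.8, mutation_prob = 0.2,
                      crossover = c("single", "uniform")) {
  stopifnot(population >= 2, iterations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 crossover = match.arg(crossover)),
            class = "ga_params")
}

#' Genetic-algorithm baseline
#'
#' Generational binary GA over selection masks, sharing
#' [evaluate_selection()] with the ALO solver: roulette-wheel parent
#' selection (same negative-fitness shift), crossover with the given
#' probability, a single-bit flip per offspring with the mutation
#' probability, and elitist carry-over of the best individual.
#'
#' @param M an `exchange_set`.
#' @param params a [ga_params()] list.
#' @param lambda penalty weight.
#' @param seed optional integer seed.
#' @return a `kpd_solution` with the best-ever individual and a
#'   non-decreasing best-fitness `trace`.
#' @export
ga_solve <- function(M, params = ga_params(), lambda = default_lambda(M),
                     seed = NULL) {
  stopifnot(inherits(M, "exchange_set"))
  if (!is.null(seed)) set.seed(seed)
  d <- length(M$exchanges)
  if (d == 0)
    return(new_kpd_solution(integer(), M, lambda, "ga", trace = numeric()))

  usage <- exchange_usage(M)
  np <- params$population
  pop <- matrix(sample(0:1, np * d, replace = TRUE), np, d)
  fit <- batch_fitness(pop, usage, lambda, graded = TRUE)$fitness
  best_i <- which.max(fit)
  best <- pop[best_i, ]
  best_fit <- fit[best_i]
  trace <- numeric(params$iterations)

  for (gen in seq_len(params$iterations)) {
    parents <- roulette_select(fit, 2 * np)
    p1 <- pop[parents[seq_len(np)], , drop = FALSE]
    p2 <- pop[parents[np + seq_len(np)], , drop = FALSE]
    cross <- stats::runif(np) < params$crossover_prob
    child <- p1
    if (d >= 2 && any(cross)) {
      if (params$crossover == "single") {
        pts <- sample.int(d - 1, np, replace = TRUE)
        for (i in which(cross))
          child[i, (pts[i] + 1):d] <- p2[i, (pts[i] + 1):d]
      } else {
        mask <- matrix(stats::runif(np * d) < 0.5, np, d)
        child[cross & mask] <- p2[cross & mask]
      }
    }
    mut <- stats::runif(np) < params$mutation_prob
    if (any(mut)) {
      idx <- cbind(which(mut), sample.int(d, sum(mut), replace = TRUE))
      child[idx] <- 1L - child[idx]
    }
    # elitism: the incumbent replaces the first offspring
    child[1, ] <- best
    pop <- child
    fit <- batch_fitness(pop, usage, lambda, graded = TRUE)$fitness
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fit) {
      best <- pop[gen_best, ]
      best_fit <- fit[gen_best]
    }
    trace[gen] <- best_fit
  }
  new_kpd_solution(best, M, lambda, "ga", trace = trace, seed = seed)
}
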