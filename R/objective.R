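# Penalized set-packing objective shared by all solvers.  A candidate
# solution is a binary mask over the exchange set M; its fitness is the
# summed utility of the selected exchanges minus lambda per node that is
# used more than once across them.

check_selection <- function(selection, M) {
  stopifnot(inherits(M, "exchange_set"))
  if (length(selection) != length(M$exchanges))
    stop("selection length (", length(selection),
         ") does not match |M| (", length(M$exchanges), ")")
  if (length(selection) && !all(selection %in% c(0, 1)))
    stop("selection entries must be 0 or 1")
  as.integer(selection)
}

#' Decode a selection vector
#'
#' Returns the exchanges of `M` at the positions where `selection` is 1,
#' in dimension order.
#'
#' @param selection binary vector of length `|M|`.
#' @param M an `exchange_set`.
#' @return list of exchanges.
#' @export
decode_selection <- function(selection, M) {
  selection <- check_selection(selection, M)
  M$exchanges[selection == 1]
}

# Node-usage incidence matrices of an exchange set.
#
# D[v, e] = 1 when node v donates a kidney if exchange e is performed.
# Every node of an exchange donates: the altruistic donor starts the
# chain, interior pairs donate to the next node, the terminal pair of a
# chain becomes a bridge donor to the deceased-donor waiting list, and
# every pair of a cycle donates to its successor.
#
# P[v, e] = 1 when node v's patient receives a kidney: every pair node
# of a chain or cycle (altruistic nodes have no patient).
exchange_usage <- function(M) {
  ex <- M$exchanges
  node_ids <- sort(unique(unlist(lapply(ex, `[[`, "nodes"))))
  d <- length(ex)
  D <- matrix(0L, length(node_ids), d)
  P <- matrix(0L, length(node_ids), d)
  for (e in seq_len(d)) {
    idx <- match(ex[[e]]$nodes, node_ids)
    D[idx, e] <- 1L
    recv <- if (ex[[e]]$kind == "chain") idx[-1] else idx
    P[recv, e] <- 1L
  }
  list(node_ids = node_ids, D = D, P = P,
       tD = t(D), tP = t(P),
       util = exchange_utilities(M))
}

# Default penalty weight: well above the pool size, here proxied by the
# number of distinct nodes occurring in M (the exchange set does not
# know the full pool); round-level drivers pass 10 * pool size exactly.
default_lambda <- function(M) {
  n <- length(unique(unlist(lapply(M$exchanges, `[[`, "nodes"))))
  10 * max(n, 1)
}

# Vectorized fitness of many masks at once: X is a n_individuals x |M|
# binary matrix; returns a list of per-row components.  The patient-side
# count is only needed for a full breakdown: every node of a selected
# exchange donates (P is entrywise dominated by D), so a patient-only
# conflict cannot occur and the solvers skip that product.
#
# graded = TRUE is the solvers' search objective: the penalty counts
# excess uses per node (a node used c times costs (c - 1) * lambda)
# instead of violating nodes.  Both agree wherever no node is used more
# than twice -- in particular on every feasible or single-conflict mask
# -- but the graded form leaves no infeasible single-flip plateau:
# dropping an exchange at an over-used node always pays, which the
# bit-flip search needs in order to descend to feasibility.
batch_fitness <- function(X, usage, lambda, breakdown = FALSE,
                          graded = FALSE) {
  utility <- as.vector(X %*% usage$util)
  if (nrow(usage$D)) {
    cnt <- X %*% usage$tD
    if (graded) {
      E1 <- rowSums(pmax(cnt - 1, 0))
      E2 <- numeric(nrow(X))
    } else {
      over_d <- cnt > 1
      E1 <- rowSums(over_d)
      E2 <- if (breakdown) rowSums(!over_d & X %*% usage$tP > 1)
            else numeric(nrow(X))
    }
  } else {
    E1 <- E2 <- numeric(nrow(X))
  }
  list(utility = utility, E1 = E1, E2 = E2,
       fitness = utility - (E1 + E2) * lambda)
}

#' Evaluate the penalized fitness of a selection
#'
#' The fitness is the total utility of the selected exchanges minus a
#' penalty `(E1 + E2) * lambda`.  Each node may take part in at most one
#' exchange; a node used in several selected exchanges is counted once,
#' in `E1` if its donor donates more than once (a chain's terminal pair
#' counts as a donor, since it bridges to the deceased-donor waiting
#' list), otherwise in `E2` if its patient receives more than once.
#' With unit weights the fitness of a feasible selection equals its
#' transplant count.
#'
#' @inheritParams decode_selection
#' @param lambda positive penalty weight; should greatly exceed the pool
#'   size so that any infeasible selection scores below any feasible
#'   one.  Defaults to 10 times the number of distinct nodes in `M`.
#' @return object of class `kpd_fitness`: list with `utility`, `E1`,
#'   `E2`, `E`, `fitness` and `feasible`.
#' @examples
#' M <- make_worked_instance()
#' evaluate_selection(c(1, 1, 0, 1), M, lambda = 50)$fitness  # -44
#' evaluate_selection(c(0, 1, 0, 1), M, lambda = 50)$fitness  # 5
#' @export
evaluate_selection <- function(selection, M, lambda = default_lambda(M)) {
  selection <- check_selection(selection, M)
  stopifnot(lambda > 0)
  if (!length(selection))
    return(structure(list(utility = 0, E1 = 0L, E2 = 0L, E = 0,
                          fitness = 0, feasible = TRUE),
                     class = "kpd_fitness"))
  usage <- exchange_usage(M)
  b <- batch_fitness(matrix(selection, 1), usage, lambda, breakdown = TRUE)
  structure(list(utility = b$utility, E1 = as.integer(b$E1),
                 E2 = as.integer(b$E2), E = (b$E1 + b$E2) * lambda,
                 fitness = b$fitness, feasible = b$E1 + b$E2 == 0),
            class = "kpd_fitness")
}

#' @export
print.kpd_fitness <- function(x, ...) {
  cat("fitness ", x$fitness, " (utility ", x$utility, ", E1 = ", x$E1,
      ", E2 = ", x$E2, ", ", if (x$feasible) "feasible" else "infeasible",
      ")\n", sep = "")
  invisible(x)
}

#' Feasibility of a selection
#'
#' A selection is feasible when the selected exchanges are pairwise
#' node-disjoint, i.e. every node donates at most once and receives at
#' most once (`E1 = E2 = 0`).
#'
#' @inheritParams decode_selection
#' @return logical.
#' @export
is_feasible <- function(selection, M) {
  selection <- check_selection(selection, M)
  nodes <- unlist(lapply(M$exchanges[selection == 1], `[[`, "nodes"))
  !anyDuplicated(nodes)
}
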