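# Greedy repair of heuristic solutions: add every exchange that is
# node-disjoint from the current solution, then try utility-improving
# single-exchange swaps.  Both phases scan M in descending-utility
# order (ties by dimension index) so the result is deterministic.

pp_scan_order <- function(M) {
  u <- exchange_utilities(M)
  order(-u, seq_along(u))
}

exchange_nodes <- function(M) lapply(M$exchanges, `[[`, "nodes")

#' Greedily augment a feasible solution
#'
#' Adds, in descending-utility order, every exchange of `M` that is
#' node-disjoint from the growing solution.  The result is maximal: no
#' unselected exchange remains disjoint from it.
#'
#' @param selection feasible binary vector over `M`.
#' @param M an `exchange_set`.
#' @return augmented binary selection.
#' @export
augment_solution <- function(selection, M) {
  selection <- check_selection(selection, M)
  if (!is_feasible(selection, M))
    stop("augment_solution requires a feasible (node-disjoint) solution")
  nodes <- exchange_nodes(M)
  used <- unlist(nodes[selection == 1])
  for (i in pp_scan_order(M)) {
    if (!selection[i] && !any(nodes[[i]] %in% used)) {
      selection[i] <- 1L
      used <- c(used, nodes[[i]])
    }
  }
  selection
}

#' Single-exchange improving swaps
#'
#' One full pass over unselected exchanges in descending-utility order:
#' an unselected exchange replaces a selected one of strictly lower
#' utility whenever it is node-disjoint from the rest of the solution.
#' Utility never decreases and feasibility is preserved.
#'
#' @inheritParams augment_solution
#' @return improved binary selection.
#' @export
swap_improve <- function(selection, M) {
  selection <- check_selection(selection, M)
  if (!is_feasible(selection, M))
    stop("swap_improve requires a feasible (node-disjoint) solution")
  nodes <- exchange_nodes(M)
  u <- exchange_utilities(M)
  ord <- pp_scan_order(M)
  for (i in ord) {
    if (selection[i]) next
    for (j in ord) {
      if (!selection[j] || u[i] <= u[j]) next
      rest <- unlist(nodes[selection == 1 & seq_along(selection) != j])
      if (!any(nodes[[i]] %in% rest)) {
        selection[j] <- 0L
        selection[i] <- 1L
        break
      }
    }
  }
  selection
}

#' Post-process a heuristic solution
#'
#' Runs the greedy augmentation, then the swap pass.  A successful swap
#' can strictly shrink the set of used nodes, so by default a second
#' augmentation pass follows (`final_augment = FALSE` restricts the
#' procedure to the single augment-swap sweep).  Utility never
#' decreases; the number of disjointness trials is bounded by
#' `|M| + |M| * |solution|` per pass.
#'
#' @inheritParams augment_solution
#' @param final_augment run a second augmentation after swapping.
#' @return post-processed binary selection.
#' @export
postprocess_solution <- function(selection, M, final_augment = TRUE) {
  out <- swap_improve(augment_solution(selection, M), M)
  if (final_augment) out <- augment_solution(out, M)
  out
}
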