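# Exchange enumeration: all chains (simple paths rooted at an altruistic
# donor) and cycles (simple directed cycles over pair nodes) up to a
# length bound k.  The resulting ordered list M fixes the dimensions of
# the binary optimizers, so its order must be reproducible.

new_exchange <- function(kind, nodes, utility) {
  list(kind = kind, nodes = as.integer(nodes), utility = as.numeric(utility))
}

new_exchange_set <- function(exchanges, k) {
  structure(list(exchanges = exchanges, k = as.integer(k)),
            class = "exchange_set")
}

#' @export
length.exchange_set <- function(x) length(x$exchanges)

#' @export
print.exchange_set <- function(x, ...) {
  kinds <- vapply(x$exchanges, `[[`, "", "kind")
  cat("Exchange set: ", length(x$exchanges), " exchanges (",
      sum(kinds == "chain"), " chains, ", sum(kinds == "cycle"),
      " cycles), k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Utilities of the exchanges in a set
#' @param M an `exchange_set`.
#' @return numeric vector of per-exchange utilities, in dimension order.
#' @export
exchange_utilities <- function(M) {
  vapply(M$exchanges, `[[`, numeric(1), "utility")
}

cmatrix_adjacency <- function(v) {
  lapply(seq_len(nrow(v)), function(i) which(v[i, ] > 0))
}

arc_sum <- function(v, nodes_idx, close = FALSE) {
  s <- 0
  if (length(nodes_idx) > 1)
    s <- sum(v[cbind(nodes_idx[-length(nodes_idx)], nodes_idx[-1])])
  if (close) s <- s + v[nodes_idx[length(nodes_idx)], nodes_idx[1]]
  s
}

#' Extract all chains up to length k
#'
#' A chain is a simple directed path rooted at an altruistic donor; the
#' bound `k` counts nodes including the altruistic donor, so a chain of
#' length L produces L - 1 transplants.  Every prefix of a longer chain
#' is itself reported as a chain.
#'
#' @param v a `kpd_cmatrix` from [build_compat_matrix()].
#' @param k maximum number of nodes per chain, `k >= 2`.
#' @return list of exchanges (`kind`, `nodes`, `utility`), unsorted.
#' @export
extract_chains <- function(v, k = 3) {
  stopifnot(k >= 2)
  ids <- attr(v, "node_ids")
  kind <- attr(v, "node_kind")
  adj <- cmatrix_adjacency(v)
  out <- list()
  dfs <- function(path, visited) {
    if (length(path) >= 2)
      out[[length(out) + 1]] <<- new_exchange("chain", ids[path],
                                              arc_sum(v, path))
    if (length(path) == k) return()
    for (nxt in adj[[path[length(path)]]])
      if (!visited[nxt]) {
        visited[nxt] <- TRUE
        dfs(c(path, nxt), visited)
        visited[nxt] <- FALSE
      }
  }
  for (root in which(kind == "altruistic")) {
    visited <- logical(length(ids))
    visited[root] <- TRUE
    dfs(root, visited)
  }
  out
}

#' Extract all cycles up to length k
#'
#' A cycle is a simple directed cycle over pair nodes; `k` bounds the
#' number of pairs, and a cycle of L pairs produces L transplants.  Each
#' cycle is reported exactly once, in its canonical rotation (minimum
#' node id first).
#'
#' @inheritParams extract_chains
#' @return list of exchanges, unsorted.
#' @export
extract_cycles <- function(v, k = 3) {
  stopifnot(k >= 2)
  ids <- attr(v, "node_ids")
  adj <- cmatrix_adjacency(v)
  out <- list()
  n <- length(ids)
  # Rooting each search at the smallest index of the cycle and only
  # descending into larger indices yields every cycle exactly once,
  # already in canonical rotation.
  dfs <- function(root, path, visited) {
    cur <- path[length(path)]
    if (length(path) >= 2 && v[cur, root] > 0)
      out[[length(out) + 1]] <<- new_exchange("cycle", ids[path],
                                              arc_sum(v, path, close = TRUE))
    if (length(path) == k) return()
    for (nxt in adj[[cur]])
      if (nxt > root && !visited[nxt]) {
        visited[nxt] <- TRUE
        dfs(root, c(path, nxt), visited)
        visited[nxt] <- FALSE
      }
  }
  for (root in seq_len(n)) {
    visited <- logical(n)
    visited[root] <- TRUE
    dfs(root, root, visited)
  }
  out
}

order_exchanges <- function(ex) {
  if (!length(ex)) return(ex)
  len <- vapply(ex, function(e) length(e$nodes), integer(1))
  key <- vapply(ex, function(e)
    paste(formatC(e$nodes, width = 12, flag = "0"), collapse = ","), "")
  ex[order(len, key)]
}

#' Enumerate the full exchange set of a pool
#'
#' Runs [extract_chains()] and [extract_cycles()] and concatenates the
#' results, chains first, each group sorted by (length, node sequence).
#' The resulting index order defines the optimizer dimensions.
#'
#' @inheritParams extract_chains
#' @return an `exchange_set`.
#' @export
enumerate_exchanges <- function(v, k = 3) {
  stopifnot(k >= 2)
  new_exchange_set(c(order_exchanges(extract_chains(v, k)),
                     order_exchanges(extract_cycles(v, k))), k)
}

#' The four-exchange worked instance
#'
#' A small fixture of four exchanges over 8 nodes used throughout the
#' documentation and tests: a 1-transplant chain A, a 2-transplant chain
#' B, a 2-cycle C and a 3-cycle D, all with unit arc weights.  The pair
#' node receiving from chain A's altruistic donor also donates inside
#' cycle D (so A and D conflict), and cycle C shares one pair with cycle
#' D.  The global optimum is utility 5, attained by B + D or by
#' A + B + C; with penalty weight 50, the mask selecting A, B and D
#' scores 6 - 50 = -44 because the shared pair donates twice.
#'
#' Node ids: pairs 0-5 (0 shared by A and D, 4 shared by C and D),
#' altruistic donors 7, 8.
#'
#' @return an `exchange_set` of dimension 4 in order
#'   `[chain A, chain B, cycle C, cycle D]`, utilities `c(1, 2, 2, 3)`.
#' @export
make_worked_instance <- function() {
  new_exchange_set(list(
    new_exchange("chain", c(7L, 0L), 1),         # A: altruistic -> shared pair
    new_exchange("chain", c(8L, 1L, 2L), 2),     # B
    new_exchange("cycle", c(3L, 4L), 2),         # C
    new_exchange("cycle", c(0L, 4L, 5L), 3)      # D: pair 0 donates here too
  ), 3L)
}

#' Exchange-set serialization as JSON lines
#'
#' One JSON object per line with fields `kind`, `nodes`, `utility`, so
#' solver runs can be replayed without re-enumeration.
#'
#' @param M an `exchange_set`.
#' @param path file path.
#' @param k length bound recorded on read (stored in a header line).
#' @return `read_exchanges()` returns an `exchange_set`;
#'   `write_exchanges()` returns `path` invisibly.
#' @export
write_exchanges <- function(M, path) {
  stopifnot(inherits(M, "exchange_set"))
  header <- jsonlite::toJSON(list(k = M$k), auto_unbox = TRUE)
  lines <- vapply(M$exchanges, function(e)
    as.character(jsonlite::toJSON(
      list(kind = e$kind, nodes = e$nodes, utility = e$utility),
      auto_unbox = TRUE, digits = NA)), "")
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' @rdname write_exchanges
#' @export
read_exchanges <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  ex <- lapply(lines[-1], function(l) {
    x <- jsonlite::fromJSON(l)
    new_exchange(x$kind, x$nodes, x$utility)
  })
  new_exchange_set(ex, header$k)
}
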