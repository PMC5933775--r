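# Independent reference implementations used to cross-check the package:
# igraph-based simple-path search for chains, combinatorial
# subset-times-rotation enumeration for cycles, and full 2^|M| mask
# enumeration for the exact solver.  These deliberately share no code
# with the package's DFS/branch-and-bound routines.

# Random pool with arbitrary arcs (blood groups are placeholders; the
# relation structure is what the enumeration and solvers consume).
random_pool <- function(n_pairs, n_alt, p_arc, seed) {
  set.seed(seed)
  n <- n_pairs + n_alt
  nodes <- data.frame(
    id = seq_len(n) - 1L,
    kind = c(rep("pair", n_pairs), rep("altruistic", n_alt)),
    donor_blood = sample(c("A", "B", "AB", "O"), n, replace = TRUE),
    patient_blood = c(sample(c("A", "B", "AB", "O"), n_pairs, replace = TRUE),
                      rep(NA_character_, n_alt)),
    stringsAsFactors = FALSE)
  from <- rep(seq_len(n) - 1L, each = n_pairs)
  to <- rep(seq_len(n_pairs) - 1L, times = n)
  keep <- from != to & runif(length(from)) < p_arc
  kpd_pool(nodes, data.frame(donor = from[keep], patient = to[keep],
                             weight = 1))
}

# All chains via igraph simple-path search from each altruistic root.
oracle_chains <- function(pool, k) {
  g <- pool_to_igraph(pool)
  roots <- pool$nodes$id[pool$nodes$kind == "altruistic"]
  out <- list()
  for (r in roots) {
    paths <- igraph::all_simple_paths(g, from = as.character(r),
                                      mode = "out", cutoff = k - 1)
    for (p in paths) {
      ids <- as.integer(names(p))
      if (length(ids) >= 2) out[[length(out) + 1]] <- ids
    }
  }
  out
}

# All cycles over pair nodes by checking every subset and rotation.
oracle_cycles <- function(pool, k) {
  arcs <- paste(pool$relations$donor, pool$relations$patient)
  has_arc <- function(a, b) paste(a, b) %in% arcs
  pairs <- sort(pool$nodes$id[pool$nodes$kind == "pair"])
  out <- list()
  for (L in 2:k) {
    if (length(pairs) < L) break
    for (subset in utils::combn(pairs, L, simplify = FALSE)) {
      root <- subset[1]   # sorted, so root is the minimum id
      rest <- subset[-1]
      perms <- if (length(rest) == 1) list(rest) else {
        idx <- expand.grid(rep(list(seq_along(rest)), length(rest)))
        idx <- idx[apply(idx, 1, function(r) !anyDuplicated(r)), ,
                   drop = FALSE]
        lapply(seq_len(nrow(idx)),
               function(i) rest[as.integer(idx[i, ])])
      }
      for (pm in perms) {
        seqn <- c(root, pm)
        ok <- all(mapply(has_arc, seqn, c(seqn[-1], root)))
        if (ok) out[[length(out) + 1]] <- seqn
      }
    }
  }
  out
}

# Exhaustive optimum over all 2^|M| masks (|M| <= ~20).
brute_force_optimum <- function(M) {
  d <- length(M)
  if (d == 0) return(0)
  best <- 0
  u <- exchange_utilities(M)
  for (code in 0:(2^d - 1)) {
    mask <- as.integer(intToBits(code)[1:d])
    if (is_feasible(mask, M)) best <- max(best, sum(u[mask == 1]))
  }
  best
}

# Canonical string form of a node sequence list, order-insensitive.
seq_key <- function(lst) sort(vapply(lst, paste, "", collapse = ","))

# A random feasible mask: scan a shuffled dimension order, keeping
# node-disjoint exchanges with probability 1/2.
random_feasible_mask <- function(M) {
  d <- length(M)
  sel <- integer(d)
  used <- integer()
  for (i in sample.int(d)) {
    nd <- M$exchanges[[i]]$nodes
    if (!any(nd %in% used) && runif(1) < 0.5) {
      sel[i] <- 1L
      used <- c(used, nd)
    }
  }
  sel
}
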