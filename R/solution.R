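# Common result container shared by the ALO, GA and exact solvers.

new_kpd_solution <- function(selection, M, lambda, method,
                             trace = NULL, seed = NULL) {
  fit <- evaluate_selection(selection, M, lambda)
  structure(list(selection = as.integer(selection),
                 exchanges = decode_selection(selection, M),
                 utility = fit$utility, fitness = fit,
                 feasible = fit$feasible, method = method,
                 trace = trace, lambda = lambda, seed = seed,
                 n_exchanges = length(M$exchanges)),
            class = "kpd_solution")
}

#' @export
print.kpd_solution <- function(x, ...) {
  cat("KPD solution (", x$method, "): ", sum(x$selection), " of ",
      x$n_exchanges, " exchanges selected, utility ", x$utility,
      if (!x$feasible) " [INFEASIBLE]", "\n", sep = "")
  invisible(x)
}

#' @export
summary.kpd_solution <- function(object, ...) {
  print(object)
  for (e in object$exchanges)
    cat("  ", e$kind, " [", paste(e$nodes, collapse = " -> "),
        if (e$kind == "cycle") " -> ...", "] utility ", e$utility,
        "\n", sep = "")
  if (!is.null(object$trace))
    cat("  elite fitness: first ", object$trace[1], ", final ",
        object$trace[length(object$trace)], " over ",
        length(object$trace), " generations\n", sep = "")
  invisible(object)
}

#' Plot the convergence trace of a stochastic solver
#'
#' @param x a `kpd_solution` with a per-generation elite-fitness trace.
#' @param ... passed to [plot()].
#' @export
plot.kpd_solution <- function(x, ...) {
  if (is.null(x$trace)) stop("this solution has no convergence trace")
  plot(seq_along(x$trace), x$trace, type = "s",
       xlab = "generation", ylab = "elite fitness",
       main = paste("Convergence,", x$method), ...)
  invisible(x)
}

#' Write a convergence trace as CSV
#'
#' @param solution a `kpd_solution` carrying a trace.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(solution, path) {
  if (is.null(solution$trace)) stop("solution has no trace")
  utils::write.csv(data.frame(generation = seq_along(solution$trace),
                              elite_fitness = solution$trace),
                   path, row.names = FALSE)
  invisible(path)
}
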