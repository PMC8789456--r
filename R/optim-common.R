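# Shared plumbing for the bounded population optimizers (SOA, DHO).

check_bounds <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) == 0L || length(lower) != length(upper)) {
    stop("`lower` and `upper` must be non-empty and of equal length", call. = FALSE)
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || any(lower >= upper)) {
    stop("bounds must be finite with lower < upper in every dimension", call. = FALSE)
  }
  list(lower = lower, upper = upper, d = length(lower))
}

clip_positions <- function(P, lower, upper) {
  P <- sweep(P, 2L, lower, pmax)
  sweep(P, 2L, upper, pmin)
}

# Evaluate the objective row-wise. `sense` decides the comparison direction.
# Non-finite values are demoted to the worst possible fitness; an error is
# raised only when no agent is finite.
eval_fitness <- function(fn, P, sense) {
  f <- vapply(seq_len(nrow(P)), function(i) {
    v <- tryCatch(fn(P[i, ]), error = function(e) NaN)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) NaN else as.numeric(v)
  }, numeric(1))
  # NaN/NA (including objective errors) count as the worst fitness for the
  # given sense; an explicit -Inf under maximization (or Inf under
  # minimization) is already worst and kept as-is.
  f[is.nan(f)] <- worst_value(sense)
  f
}

better_than <- function(a, b, sense) {
  if (sense == "minimize") a < b else a > b
}

worst_value <- function(sense) if (sense == "minimize") Inf else -Inf

init_population <- function(m, lower, upper) {
  d <- length(lower)
  P <- matrix(stats::runif(m * d), m, d)
  sweep(sweep(P, 2L, upper - lower, `*`), 2L, lower, `+`)
}

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

new_opt_result <- function(method, best_position, best_fitness, history, params, sense) {
  structure(
    list(
      method = method,
      best_position = as.numeric(best_position),
      best_fitness = as.numeric(best_fitness),
      history = tibble::tibble(
        iteration = seq_along(history),
        best_fitness = as.numeric(history)
      ),
      params = params,
      sense = sense
    ),
    class = "swarm_opt"
  )
}

#' @export
print.swarm_opt <- function(x, ...) {
  cat(sprintf(
    "<swarm_opt> %s (%s), %d iterations\n  best fitness: %.6g\n  best position: %s\n",
    toupper(x$method), x$sense, nrow(x$history), x$best_fitness,
    paste(signif(x$best_position, 6), collapse = ", ")
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the convergence history of an optimizer run
#'
#' @param x a `swarm_opt` object from [soa_optimize()] or [dho_optimize()].
#' @param ... unused.
#' @return A tibble with columns `iteration` and `best_fitness`
#'   (best-so-far, monotone by the elitism contract).
#' @export
tidy.swarm_opt <- function(x, ...) x$history

#' @rdname tidy.swarm_opt
#' @export
glance.swarm_opt <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    sense = x$sense,
    iterations = nrow(x$history),
    best_fitness = x$best_fitness,
    dimensions = length(x$best_position)
  )
}

#' Convergence plot for an optimizer run
#'
#' @param object a `swarm_opt` object.
#' @param ... unused.
#' @return A ggplot of best-so-far fitness against iteration.
#' @export
autoplot.swarm_opt <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "iteration", y = "best-so-far fitness",
      title = sprintf("%s convergence", toupper(object$method))
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
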