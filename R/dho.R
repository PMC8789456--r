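#' Deer hunting optimization (DHO)
#'
#' A population metaheuristic modelled on a party of hunters encircling
#' deer. Hunters are guided by the best-so-far position (the leader `X_l`)
#' and the second-best of the current population (the successor `X_s`).
#' Each iteration draws a wind angle `theta = 2*pi*a` with `a ~ U[0,1]` and
#' coefficient vectors `Z = (1/4) * log(j + 1/j_max) * b` with
#' `b ~ U[-1, 1]` and `K = 2c` with `c ~ U[0, 1]`; every hunter draws its
#' own wind-speed factor `p ~ U[0, 2]`. The position update branches:
#'
#' * `|K| < 1`: global search via the successor,
#'   `X' = X_s - Z * p * |K * X_s - X|`;
#' * else if `p < 1`: encircling the leader,
#'   `X' = X_l - Z * p * |K * X_l - X|`;
#' * else: the angle update `X' = X_l - p * cos(theta) * |X_l - X|`,
#'   which widens the search around the leader.
#'
#' Positions are clipped to the box; the leader is elitist (replaced only
#' on strict improvement), so the best-so-far history is monotone.
#'
#' @param population number of hunters `m` (>= 2).
#' @param iterations maximum iteration count `j_max`.
#' @param seed optional integer seed for bit-reproducible runs.
#' @return `dho_params()` returns a parameter list for [dho_optimize()].
#' @examples
#' res <- dho_optimize(function(x) (x - 3)^2, lower = 0, upper = 10,
#'                     params = dho_params(population = 15, iterations = 100, seed = 1))
#' res$best_position
#' @export
dho_params <- function(population = 30L, iterations = 100L, seed = NULL) {
  population <- as.integer(population)
  iterations <- as.integer(iterations)
  if (population < 2L) stop("`population` must be >= 2", call. = FALSE)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  list(population = population, iterations = iterations, seed = seed)
}

#' Initialize DHO state
#'
#' @inheritParams soa_init
#' @param params from [dho_params()].
#' @return A state list with positions `X`, fitness, leader (`best`,
#'   `best_fitness`), successor (`successor`), and iteration counter `j`.
#' @export
dho_init <- function(objective, lower, upper, params = dho_params(),
                     sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  b <- check_bounds(lower, upper)
  X <- init_population(params$population, b$lower, b$upper)
  f <- eval_fitness(objective, X, sense)
  if (all(!is.finite(f))) {
    stop("objective returned no finite value on the initial population", call. = FALSE)
  }
  ord <- order(f, decreasing = (sense == "maximize"))
  list(
    X = X, fitness = f,
    best = X[ord[1L], ], best_fitness = f[ord[1L]],
    successor = X[ord[2L], ], successor_fitness = f[ord[2L]],
    lower = b$lower, upper = b$upper, sense = sense, j = 0L
  )
}

#' One DHO sweep over all hunters
#'
#' @inheritParams dho_init
#' @param state a state list from [dho_init()] or a previous `dho_step()`.
#' @return The updated state.
#' @export
dho_step <- function(state, params, objective) {
  m <- nrow(state$X)
  d <- ncol(state$X)
  j <- state$j + 1L
  a <- stats::runif(1)
  theta <- 2 * pi * a
  b <- stats::runif(1, -1, 1)
  cc <- stats::runif(1)
  Z <- 0.25 * log(j + 1 / params$iterations) * b
  K <- 2 * cc
  p <- stats::runif(m, 0, 2)
  Xl <- matrix(state$best, m, d, byrow = TRUE)
  Xs <- matrix(state$successor, m, d, byrow = TRUE)
  if (abs(K) < 1) {
    Xn <- Xs - Z * p * abs(K * Xs - state$X)
  } else {
    enc <- Xl - Z * p * abs(K * Xl - state$X)
    ang <- Xl - p * cos(theta) * abs(Xl - state$X)
    sel <- p < 1
    Xn <- ang
    Xn[sel, ] <- enc[sel, , drop = FALSE]
  }
  Xn <- clip_positions(Xn, state$lower, state$upper)
  f <- eval_fitness(objective, Xn, state$sense)
  state$X <- Xn
  state$fitness <- f
  state$j <- j
  ord <- order(f, decreasing = (state$sense == "maximize"))
  if (better_than(f[ord[1L]], state$best_fitness, state$sense)) {
    state$best <- Xn[ord[1L], ]
    state$best_fitness <- f[ord[1L]]
    succ <- ord[2L]
  } else {
    succ <- ord[1L]
  }
  state$successor <- Xn[succ, ]
  state$successor_fitness <- f[succ]
  state
}

#' Run deer hunting optimization
#'
#' @inheritParams dho_init
#' @return A `swarm_opt` object; see [soa_optimize()] for the fields.
#' @export
dho_optimize <- function(objective, lower, upper, params = dho_params(),
                         sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  with_opt_seed(params$seed, {
    state <- dho_init(objective, lower, upper, params, sense)
    history <- numeric(params$iterations)
    for (it in seq_len(params$iterations)) {
      state <- dho_step(state, params, objective)
      history[it] <- state$best_fitness
    }
    new_opt_result("dho", state$best, state$best_fitness, history, params, sense)
  })
}
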