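#' Seagull optimization algorithm (SOA)
#'
#' A population metaheuristic modelled on the migration and attack
#' behaviour of seagulls. Migration (exploration) moves every agent with a
#' collision-avoidance term `C_s = A * P_s` and a best-agent attraction
#' `M_s = B * (P_bs - P_s)`, where the control `A = f_c - x * f_c / X_max`
#' decays linearly from `f_c` (default 2) to 0 over the run and
#' `B = 2 * A^2 * r_d` with `r_d ~ U[0, 1]` balances exploration against
#' exploitation. Attack (exploitation) spirals around the best agent: with
#' a draw `k ~ U[0, 2*pi]` and spiral radius `u * exp(k * v)`, the new
#' position is `P_s = D_s * (r cos k)(r sin k)(r k) + P_bs` with distance
#' `D_s = |C_s + M_s|`. The best-so-far position is elitist: it is replaced
#' only by a strictly better fitness, so the reported history is monotone.
#'
#' @param population number of search agents `m` (>= 2).
#' @param iterations maximum iteration count.
#' @param fc frequency control for `A` (default 2).
#' @param spiral_u,spiral_v spiral shape constants `u`, `v` (default 1).
#' @param seed optional integer seed; runs are bit-reproducible given the
#'   seed. The caller's RNG state is restored afterwards.
#' @return `soa_params()` returns a parameter list used by [soa_optimize()].
#' @examples
#' res <- soa_optimize(function(x) sum(x^2), lower = -5, upper = 5,
#'                     params = soa_params(population = 20, iterations = 50, seed = 1))
#' res$best_fitness
#' @export
soa_params <- function(population = 30L, iterations = 100L, fc = 2,
                       spiral_u = 1, spiral_v = 1, seed = NULL) {
  population <- as.integer(population)
  iterations <- as.integer(iterations)
  if (population < 2L) stop("`population` must be >= 2", call. = FALSE)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  if (!is.numeric(fc) || fc <= 0) stop("`fc` must be positive", call. = FALSE)
  list(
    population = population, iterations = iterations, fc = fc,
    spiral_u = spiral_u, spiral_v = spiral_v, seed = seed
  )
}

#' Initialize SOA state
#'
#' @param objective scalar objective function of a position vector.
#' @param lower,upper per-dimension box bounds.
#' @param params from [soa_params()].
#' @param sense `"minimize"` or `"maximize"`.
#' @return A state list with agent positions `P`, fitness, the best
#'   position `best` / `best_fitness`, and the iteration counter `x`.
#' @export
soa_init <- function(objective, lower, upper, params = soa_params(),
                     sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  b <- check_bounds(lower, upper)
  P <- init_population(params$population, b$lower, b$upper)
  f <- eval_fitness(objective, P, sense)
  if (all(!is.finite(f))) {
    stop("objective returned no finite value on the initial population", call. = FALSE)
  }
  i <- if (sense == "minimize") which.min(f) else which.max(f)
  list(
    P = P, fitness = f, best = P[i, ], best_fitness = f[i],
    lower = b$lower, upper = b$upper, sense = sense, x = 0L
  )
}

#' One SOA sweep over all agents
#'
#' Advances `state$x` by one and applies the migration + spiral-attack
#' update to every agent; the best position is updated synchronously at the
#' end of the sweep and only on strict improvement.
#'
#' @inheritParams soa_init
#' @param state a state list from [soa_init()] or a previous `soa_step()`.
#' @return The updated state.
#' @export
soa_step <- function(state, params, objective) {
  m <- nrow(state$P)
  d <- ncol(state$P)
  x <- state$x + 1L
  A <- params$fc - x * (params$fc / params$iterations)
  rd <- stats::runif(m)
  B <- 2 * A^2 * rd
  k <- stats::runif(m, 0, 2 * pi)
  r <- params$spiral_u * exp(k * params$spiral_v)
  spiral <- (r * cos(k)) * (r * sin(k)) * (r * k)
  Pb <- matrix(state$best, m, d, byrow = TRUE)
  Cs <- A * state$P
  Ms <- B * (Pb - state$P)
  Ds <- abs(Cs + Ms)
  P <- clip_positions(Ds * spiral + Pb, state$lower, state$upper)
  f <- eval_fitness(objective, P, state$sense)
  state$P <- P
  state$fitness <- f
  state$x <- x
  i <- if (state$sense == "minimize") which.min(f) else which.max(f)
  if (better_than(f[i], state$best_fitness, state$sense)) {
    state$best <- P[i, ]
    state$best_fitness <- f[i]
  }
  state
}

#' Run the seagull optimization algorithm
#'
#' @inheritParams soa_init
#' @return A `swarm_opt` object with `best_position`, `best_fitness`, and a
#'   monotone best-so-far `history` tibble; see [tidy.swarm_opt()].
#' @export
soa_optimize <- function(objective, lower, upper, params = soa_params(),
                         sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  with_opt_seed(params$seed, {
    state <- soa_init(objective, lower, upper, params, sense)
    history <- numeric(params$iterations)
    for (it in seq_len(params$iterations)) {
      state <- soa_step(state, params, objective)
      history[it] <- state$best_fitness
    }
    new_opt_result("soa", state$best, state$best_fitness, history, params, sense)
  })
}
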