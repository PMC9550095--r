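# Continuous-space fruit fly optimization (FFO) and its chaotic
# oppositional variant (COFFO), with exact FFE budget accounting and
# best-so-far tracing.

#' Evaluation budget implied by a population/iteration schedule
#'
#' Algorithms that evaluate the whole population once at initialization and
#' once per member per iteration spend `n * (1 + max_iter)` fitness function
#' evaluations; using this count (rather than iterations) as the termination
#' condition makes comparisons across algorithms unbiased. The conventional
#' benchmark schedule `n = 50`, `max_iter = 500` gives 25,050 FFEs; the
#' feature-selection schedule `n = 10`, `max_iter = 100` gives 1,010.
#'
#' @param pop_size Population size `n`.
#' @param max_iter Number of iterations.
#' @return The FFE budget, an integer.
#' @examples
#' ffe_budget(50, 500)  # 25050
#' ffe_budget(10, 100)  # 1010
#' @export
ffe_budget <- function(pop_size, max_iter) {
  as.integer(pop_size * (1 + max_iter))
}

#' Control parameters for the continuous optimizers
#'
#' Defaults follow the conventional benchmark settings: population size 50,
#' budget `ffe_budget(50, 500) = 25050` FFEs, logistic-map parameter 4,
#' chaotic local search of 4 steps triggered once a third of the budget is
#' spent.
#'
#' @param pop_size Population size `N` (even for COFFO's split
#'   initialization).
#' @param max_ffes Evaluation budget; default `ffe_budget(pop_size, 500)`.
#' @param cls_steps `K`, maximum chaotic-local-search evaluations per
#'   trigger.
#' @param cls_trigger FFE count after which the chaotic local search starts;
#'   default `floor(max_ffes / 3)`.
#' @param chaos_mu Logistic-map control parameter, default 4 (chaotic
#'   regime).
#' @param step_scale Half-width of the uniform osphresis step, default 1.
#' @param chaos_mode Chaotic-variant mode for initialization, see
#'   [chaotic_variant()].
#' @param seed Root seed for all random substreams.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(pop_size = 50, max_ffes = NULL, cls_steps = 4,
                             cls_trigger = NULL, chaos_mu = 4,
                             step_scale = 1,
                             chaos_mode = c("literal", "normalized"),
                             seed = 1) {
  chaos_mode <- match.arg(chaos_mode)
  if (pop_size < 1) stop("'pop_size' must be positive", call. = FALSE)
  if (is.null(max_ffes)) max_ffes <- ffe_budget(pop_size, 500)
  if (max_ffes < 1) stop("'max_ffes' must be positive", call. = FALSE)
  if (is.null(cls_trigger)) cls_trigger <- floor(max_ffes / 3)
  if (cls_trigger > max_ffes) {
    stop("'cls_trigger' cannot exceed 'max_ffes'", call. = FALSE)
  }
  if (cls_steps < 1) stop("'cls_steps' must be positive", call. = FALSE)
  if (step_scale <= 0) stop("'step_scale' must be positive", call. = FALSE)
  structure(list(pop_size = as.integer(pop_size),
                 max_ffes = as.integer(max_ffes),
                 cls_steps = as.integer(cls_steps),
                 cls_trigger = as.integer(cls_trigger),
                 chaos_mu = chaos_mu,
                 step_scale = step_scale,
                 chaos_mode = chaos_mode,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Uniform random population within a box
#'
#' @param bounds A [bounds()] object.
#' @param n Positive number of solutions.
#' @return An `n x D` matrix, each component uniform in its range.
#' @export
init_random_population <- function(bounds, n) {
  if (length(n) != 1L || n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  D <- bounds$dimension
  matrix(stats::runif(n * D, rep(bounds$lower, each = n),
                      rep(bounds$upper, each = n)), n, D)
}

#' Osphresis (smell-based) foraging step
#'
#' A candidate is placed uniformly at random in a cube of half-width
#' `step_scale` around the current position and clamped into the box. The
#' signed uniform draw in `[-1, 1]` absorbs the random walk direction.
#'
#' @param current Numeric position vector within bounds.
#' @param bounds A [bounds()] object.
#' @param step_scale Positive half-width of the step (default 1).
#' @return The clamped candidate position.
#' @export
osphresis_step <- function(current, bounds, step_scale = 1) {
  u <- stats::runif(bounds$dimension, -1, 1)
  clamp(current + step_scale * u, bounds)
}

#' Vision (swarm relocation) phase
#'
#' When the iteration produced a new global best, the whole swarm relocates
#' onto the best position; otherwise the population is left unchanged.
#'
#' @param positions `n x D` matrix of member positions.
#' @param best_position The global best position.
#' @param improved Logical: did this iteration improve the global best?
#' @return The updated position matrix.
#' @export
vision_update <- function(positions, best_position, improved) {
  if (improved) {
    positions <- matrix(best_position, nrow(positions),
                        length(best_position), byrow = TRUE)
  }
  positions
}

run_swarm <- function(problem, config, algorithm = c("ffo", "coffo")) {
  algorithm <- match.arg(algorithm)
  b <- problem$bounds
  N <- config$pop_size
  budget <- budget_counter(config$max_ffes)
  init_cost <- if (algorithm == "coffo") 2L * N else N

  if (config$max_ffes < init_cost) {
    stop("budget (", config$max_ffes, ") is smaller than the ",
         init_cost, " evaluations needed to initialize", call. = FALSE)
  }

  init <- with_seed(substream_seed(config$seed, "init"), {
    if (algorithm == "coffo") {
      chaotic_opposition_init(problem, N, budget,
                              chaos_mode = config$chaos_mode)
    } else {
      P <- init_random_population(b, N)
      fit <- evaluate_rows(problem, P, budget)
      list(positions = P, fitness = fit, random_best = min(fit))
    }
  })

  best_i <- which.min(init$fitness)
  best <- list(position = init$positions[best_i, ], fitness = init$fitness[best_i])
  pos <- init$positions

  trace_ffe <- budget$used
  trace_fit <- best$fitness

  with_seed(substream_seed(config$seed, "search"), {
    while (budget_left(budget) > 0) {
      m <- min(N, budget_left(budget))
      cand <- rows_from_vapply(vapply(seq_len(m), function(i) {
        osphresis_step(pos[i, ], b, config$step_scale)
      }, numeric(b$dimension)), b$dimension)
      fit <- evaluate_rows(problem, cand, budget)
      fit_ok <- fit[!is.na(fit)]
      improved <- length(fit_ok) > 0 && min(fit_ok) < best$fitness
      if (improved) {
        j <- which.min(fit)
        best <- list(position = cand[j, ], fitness = fit[j])
        trace_ffe <- c(trace_ffe, budget$used)
        trace_fit <- c(trace_fit, best$fitness)
      }
      pos <- vision_update(pos, best$position, improved)

      if (algorithm == "coffo" && budget$used > config$cls_trigger &&
          budget_left(budget) > 0) {
        lambda <- shrinkage(budget$used, config$max_ffes)
        res <- chaotic_local_search(best, problem, config$cls_steps,
                                    lambda, budget, mu = config$chaos_mu)
        if (res$improved) {
          best <- list(position = res$position, fitness = res$fitness)
          pos <- vision_update(pos, best$position, TRUE)
          trace_ffe <- c(trace_ffe, budget$used)
          trace_fit <- c(trace_fit, best$fitness)
        }
      }
    }
  })

  trace_ffe <- c(trace_ffe, budget$used)
  trace_fit <- c(trace_fit, best$fitness)
  keep <- !duplicated(cbind(trace_ffe, trace_fit), fromLast = TRUE)

  structure(list(
    best_position = best$position,
    best_fitness = best$fitness,
    trace = data.frame(ffe = trace_ffe[keep], best = trace_fit[keep]),
    ffes_used = budget$used,
    init_random_best = init$random_best,
    algorithm = algorithm,
    problem = problem$name,
    config = config
  ), class = "ffo_result")
}

#' Run the baseline fruit fly optimizer
#'
#' Random initialization (`N` FFEs), then repeated osphresis steps from each
#' member, evaluation, and the vision phase relocating the swarm onto any
#' new global best, until the FFE budget is exhausted.
#'
#' @param problem An `opt_problem` from [make_benchmark()].
#' @param config An [optimizer_config()].
#' @return An object of class `ffo_result`: `best_position`, `best_fitness`,
#'   a non-increasing best-so-far `trace` (data frame of FFE count and best
#'   fitness), `ffes_used`, and the diagnostics `init_random_best`,
#'   `algorithm`, `problem`, `config`.
#' @examples
#' p <- make_benchmark("sphere", dimension = 2, range = c(-5, 5))
#' run_ffo(p, optimizer_config(pop_size = 10, max_ffes = 510, seed = 7))
#' @export
run_ffo <- function(problem, config = optimizer_config()) {
  run_swarm(problem, config, "ffo")
}

#' Run the chaotic oppositional fruit fly optimizer
#'
#' As [run_ffo()], with two additions: the population is initialized by
#' [chaotic_opposition_init()] (costing `2N` FFEs), and once the spent
#' budget passes `cls_trigger`, every iteration runs a
#' [chaotic_local_search()] of at most `cls_steps` evaluations around the
#' global best, with the blend weight shrinking as the budget is consumed
#' ([shrinkage()]).
#'
#' @inheritParams run_ffo
#' @return An `ffo_result`; see [run_ffo()].
#' @export
run_coffo <- function(problem, config = optimizer_config()) {
  run_swarm(problem, config, "coffo")
}

#' @export
print.ffo_result <- function(x, ...) {
  cat(sprintf("%s on '%s': best fitness %.6g after %d FFEs\n",
              toupper(x$algorithm), x$problem, x$best_fitness, x$ffes_used))
  invisible(x)
}

#' Plot the best-so-far convergence trace
#'
#' @param x An `ffo_result`.
#' @param log Axis specification passed to [plot()] (default log-scaled y).
#' @param ... Further graphical parameters.
#' @export
plot.ffo_result <- function(x, log = if (all(x$trace$best > 0)) "y" else "", ...) {
  plot(x$trace$ffe, x$trace$best, type = "s", log = log,
       xlab = "fitness function evaluations", ylab = "best fitness",
       main = sprintf("%s on %s", toupper(x$algorithm), x$problem), ...)
  invisible(x)
}
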