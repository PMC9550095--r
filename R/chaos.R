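# Opposition-based learning, logistic chaotic sequences, the
# chaotic-opposition population initialization, and the chaotic local search
# around the global best.

#' Opposite point under opposition-based learning
#'
#' Opposition-based learning mirrors a candidate about the centre of the box:
#' the opposite of `x` is `lower + upper - x`, componentwise. Evaluating a
#' point together with its opposite roughly doubles the chance that one of
#' the pair lands near the optimum, which is why it is used during
#' population initialization.
#'
#' @param x Numeric vector (or matrix, one row per candidate) within bounds.
#' @param bounds A [bounds()] object.
#' @return The mirrored point(s), same shape as `x`.
#' @examples
#' opposite_point(3, bounds(1, 0, 10))  # 7
#' @export
opposite_point <- function(x, bounds) {
  if (is.matrix(x)) {
    if (any(x < rep(bounds$lower, each = nrow(x))) ||
        any(x > rep(bounds$upper, each = nrow(x)))) {
      stop("x must lie within bounds", call. = FALSE)
    }
    return(rep(bounds$lower + bounds$upper, each = nrow(x)) - x)
  }
  if (!in_bounds(x, bounds)) stop("x must lie within bounds", call. = FALSE)
  bounds$lower + bounds$upper - x
}

#' One step of the logistic map
#'
#' The logistic recurrence `beta <- mu * beta * (1 - beta)`. At `mu = 4` the
#' map is chaotic on (0, 1); orbits started away from the degenerate points
#' 0, 0.25, 0.5, 0.75 and 1 stay inside the open interval.
#'
#' @param beta Numeric in (0, 1) (vectorized).
#' @param mu Control parameter, default 4.
#' @return `mu * beta * (1 - beta)`.
#' @examples
#' logistic_step(0.3)        # 0.84
#' logistic_step(0.75)       # 0.75, a fixed point
#' @export
logistic_step <- function(beta, mu = 4) {
  if (any(beta <= 0) || any(beta >= 1)) {
    stop("beta must lie in the open interval (0, 1)", call. = FALSE)
  }
  mu * beta * (1 - beta)
}

# draw logistic seeds in (0,1) avoiding the degenerate orbit starts
# {0.25, 0.5, 0.75} (within 1e-12)
draw_beta0 <- function(n) {
  b <- stats::runif(n)
  bad <- pmin(abs(b - 0.25), abs(b - 0.5), abs(b - 0.75)) < 1e-12 |
    b <= 0 | b >= 1
  while (any(bad)) {
    b[bad] <- stats::runif(sum(bad))
    bad <- pmin(abs(b - 0.25), abs(b - 0.5), abs(b - 0.75)) < 1e-12 |
      b <= 0 | b >= 1
  }
  b
}

#' Chaotic variant of a solution
#'
#' Maps a solution onto a chaotic sequence `beta`. In `"literal"` mode the
#' variant is the direct product `beta * x` clamped into the box; in
#' `"normalized"` mode the chaotic value interpolates the box instead,
#' `lower + beta * (x - lower)`, which is symmetric in the bounds. Literal
#' mode is the default.
#'
#' @param x Numeric vector within bounds.
#' @param beta Numeric vector of chaotic values in (0, 1), recycled to
#'   `length(x)`.
#' @param bounds A [bounds()] object.
#' @param mode `"literal"` or `"normalized"`.
#' @return The chaotic variant, clamped to bounds.
#' @export
chaotic_variant <- function(x, beta, bounds,
                            mode = c("literal", "normalized")) {
  mode <- match.arg(mode)
  if (any(beta <= 0) || any(beta >= 1)) {
    stop("beta components must lie in (0, 1)", call. = FALSE)
  }
  beta <- rep_len(beta, length(x))
  out <- switch(mode,
    literal = beta * x,
    normalized = bounds$lower + beta * (x - bounds$lower)
  )
  clamp(out, bounds)
}

#' Budget-dependent shrinkage weight for the chaotic local search
#'
#' `lambda = (max_ffe - ffe + 1) / max_ffe`: close to 1 at the start of the
#' run (wide exploration around the global best) and `1/max_ffe` at budget
#' exhaustion (fine exploitation).
#'
#' @param ffe Current evaluation count, in `1..max_ffe`.
#' @param max_ffe Total evaluation budget.
#' @return The shrinkage weight in (0, 1].
#' @examples
#' shrinkage(1, 25050)       # 1
#' shrinkage(12526, 25050)   # 0.5
#' @export
shrinkage <- function(ffe, max_ffe) {
  if (any(ffe < 1) || any(ffe > max_ffe)) {
    stop("ffe must lie in [1, max_ffe]", call. = FALSE)
  }
  (max_ffe - ffe + 1) / max_ffe
}

#' Chaotic-opposition population initialization
#'
#' Builds an initial population of `n` solutions from `2n` evaluated
#' candidates: `n` uniform random solutions `P`; the opposites of the first
#' `n/2` members; and chaotic variants of the last `n/2` members (each
#' member contributes to exactly one derived candidate). All `2n` candidates
#' are evaluated (spending exactly `2n` FFEs), sorted by fitness with a
#' stable insertion-order tie-break, and the best `n` are kept, so the
#' returned best can never be worse than the best of the plain random
#' population alone.
#'
#' @param problem An `opt_problem`.
#' @param n Even positive population size.
#' @param budget A [budget_counter()] with at least `2n` evaluations left.
#' @param chaos_mode Passed to [chaotic_variant()].
#' @return List with `positions` (`n x D` matrix), `fitness` (length `n`,
#'   ascending), and `random_best` (best fitness within the embedded plain
#'   random population, for diagnostics).
#' @export
chaotic_opposition_init <- function(problem, n, budget,
                                    chaos_mode = c("literal", "normalized")) {
  chaos_mode <- match.arg(chaos_mode)
  if (n < 2 || n %% 2 != 0) {
    stop("population size must be even and >= 2 for the split ",
         "opposition/chaotic derivation", call. = FALSE)
  }
  b <- problem$bounds
  D <- b$dimension
  P <- matrix(stats::runif(n * D, rep(b$lower, each = n),
                           rep(b$upper, each = n)), n, D)
  half <- n / 2L
  Po <- opposite_point(P[seq_len(half), , drop = FALSE], b)
  Pc <- rows_from_vapply(vapply(seq_len(half), function(i) {
    chaotic_variant(P[half + i, ], draw_beta0(D), b, mode = chaos_mode)
  }, numeric(D)), D)
  all_pos <- rbind(P, Po, Pc)
  fit <- evaluate_rows(problem, all_pos, budget)
  if (anyNA(fit)) stop("budget exhausted during initialization", call. = FALSE)
  ord <- order(fit)  # stable: ties keep insertion order
  keep <- ord[seq_len(n)]
  list(positions = all_pos[keep, , drop = FALSE],
       fitness = fit[keep],
       random_best = min(fit[seq_len(n)]))
}

#' Chaotic local search around the global best
#'
#' Attempts to improve the incumbent best solution in at most `k_steps`
#' evaluations. A shared logistic chaotic sequence (fresh seed per
#' invocation) places a point `S = lower + beta * (upper - lower)` in the
#' box; the candidate blends it with the incumbent,
#' `x' = (1 - lambda) * x + lambda * S`. The first candidate strictly better
#' than the incumbent is returned immediately; if none improves (or the
#' budget runs out mid-search) the incumbent is returned unchanged, so the
#' search can never worsen the best solution.
#'
#' @param best List with `position` and `fitness` of the incumbent.
#' @param problem An `opt_problem`.
#' @param k_steps Maximum number of chaotic steps (candidate evaluations).
#' @param lambda Shrinkage weight from [shrinkage()].
#' @param budget A [budget_counter()].
#' @param mu Logistic-map parameter, default 4.
#' @return List with `position`, `fitness`, and `improved` (logical).
#' @export
chaotic_local_search <- function(best, problem, k_steps, lambda, budget,
                                 mu = 4) {
  b <- problem$bounds
  beta <- draw_beta0(b$dimension)
  for (k in seq_len(k_steps)) {
    if (budget$used >= budget$limit) break
    beta <- logistic_step(beta, mu)
    if (any(beta <= 0) || any(beta >= 1)) beta <- draw_beta0(b$dimension)
    S <- b$lower + beta * (b$upper - b$lower)
    cand <- clamp((1 - lambda) * best$position + lambda * S, b)
    f <- evaluate_problem(problem, cand, budget)
    if (f < best$fitness) {
      return(list(position = cand, fitness = f, improved = TRUE))
    }
  }
  list(position = best$position, fitness = best$fitness, improved = FALSE)
}
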