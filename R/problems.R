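# Self-contained bound-constrained benchmark objectives.
#
# cec01-cec03 are the data-free problems of the CEC2019 "100-digit" set
# (Storn's Chebyshev polynomial fitting, inverse Hilbert matrix,
# Lennard-Jones minimum energy). cec04-cec10 are unshifted, unrotated
# analogues of the corresponding classic functions, each offset so the
# global minimum value is 1; they are deliberately NOT bit-compatible with
# the official shifted/rotated suite, which requires external data files.

# -- elementary objectives ----------------------------------------------------

f_sphere <- function(x) sum(x^2)

f_rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)

f_griewank <- function(x) {
  1 + sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x))))
}

f_weierstrass <- function(x) {
  kmax <- 20L
  a <- 0.5^(0:kmax)
  b <- 3^(0:kmax)
  inner <- vapply(x, function(xj) sum(a * cos(2 * pi * b * (xj + 0.5))), 0)
  sum(inner) - length(x) * sum(a * cos(pi * b))
}

# modified Schwefel with internal scaling z = 5x so the minimizer
# z* = 420.9687463599820 sits inside the [-100, 100] box at x* = z*/5
.schwefel_peak <- 418.982887272433686
.schwefel_zstar <- 420.968746359982049

f_schwefel <- function(x) {
  z <- 5 * x
  .schwefel_peak * length(x) - sum(z * sin(sqrt(abs(z))))
}

f_happycat <- function(x) {
  D <- length(x)
  s2 <- sum(x^2)
  abs(s2 - D)^0.25 + (0.5 * s2 + sum(x)) / D + 0.5
}

f_ackley <- function(x) {
  D <- length(x)
  20 + exp(1) - 20 * exp(-0.2 * sqrt(sum(x^2) / D)) -
    exp(sum(cos(2 * pi * x)) / D)
}

f_schaffer_exp <- function(x) {
  xn <- c(x[-1], x[1])
  s2 <- x^2 + xn^2
  sum(0.5 + (sin(sqrt(s2))^2 - 0.5) / (1 + 0.001 * s2)^2)
}

# -- CEC2019-style data-free problems ----------------------------------------

# Storn's Chebyshev polynomial fitting, D coefficients (degree D - 1)
f_chebyshev <- function(x) {
  D <- length(x)
  # T_{D-1}(1.2) by the Chebyshev recursion
  a <- 1
  b <- 1.2
  for (i in seq_len(D - 2L)) {
    dz <- 2.4 * b - a
    a <- b
    b <- dz
  }
  dx <- b
  m <- 32L * D
  y <- -1 + 2 * (0:m) / m
  # Horner evaluation of the polynomial at all sample points
  px <- rep(x[1], m + 1L)
  for (j in 2:D) px <- px * y + x[j]
  res <- sum((1 - abs(px))[abs(px) > 1]^2)
  for (yy in c(-1.2, 1.2)) {
    pv <- x[1]
    for (j in 2:D) pv <- pv * yy + x[j]
    if (pv < dx) res <- res + (pv - dx)^2
  }
  res + 1
}

# inverse Hilbert matrix problem: x filled into an n x n matrix Z, n = sqrt(D)
f_inv_hilbert <- function(x) {
  n <- as.integer(round(sqrt(length(x))))
  H <- 1 / (outer(seq_len(n), seq_len(n), `+`) - 1)
  Z <- matrix(x, n, n, byrow = TRUE)
  sum(abs(H %*% Z - diag(n))) + 1
}

# Lennard-Jones minimum-energy cluster of D/3 atoms, pair potential
# r^-12 - 2 r^-6; offset by the known 6-atom minimum energy so f* ~ 1
f_lennard_jones <- function(x) {
  atoms <- matrix(x, ncol = 3L, byrow = TRUE)
  n <- nrow(atoms)
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d2 <- sum((atoms[i, ] - atoms[j, ])^2)
      d2 <- max(d2, 1e-12)  # minimum-distance guard on random points
      r6 <- d2^-3
      e <- e + (r6^2 - 2 * r6)
    }
  }
  1 + 12.7120622568 + e
}

# -- registry -----------------------------------------------------------------

problem_registry <- function() {
  list(
    cec01 = list(f = f_chebyshev, D = 9L, range = c(-8192, 8192),
                 optimum = 1, minimizer = NULL,
                 desc = "Storn's Chebyshev polynomial fitting"),
    cec02 = list(f = f_inv_hilbert, D = 16L, range = c(-16384, 16384),
                 optimum = 1, minimizer = NULL,
                 desc = "inverse Hilbert matrix"),
    cec03 = list(f = f_lennard_jones, D = 18L, range = c(-4, 4),
                 optimum = 1, minimizer = NULL,
                 desc = "Lennard-Jones minimum energy (6 atoms)"),
    cec04 = list(f = function(x) 1 + f_rastrigin(x), D = 10L,
                 range = c(-100, 100), optimum = 1, minimizer = 0,
                 desc = "Rastrigin analogue (unshifted, +1)"),
    cec05 = list(f = function(x) 1 + f_griewank(x), D = 10L,
                 range = c(-100, 100), optimum = 1, minimizer = 0,
                 desc = "Griewank analogue (unshifted, +1)"),
    cec06 = list(f = function(x) 1 + f_weierstrass(x), D = 10L,
                 range = c(-100, 100), optimum = 1, minimizer = 0,
                 desc = "Weierstrass analogue (unshifted, +1)"),
    cec07 = list(f = function(x) 1 + f_schwefel(x), D = 10L,
                 range = c(-100, 100), optimum = 1,
                 minimizer = .schwefel_zstar / 5,
                 desc = "modified Schwefel analogue (scaled, +1)"),
    cec08 = list(f = function(x) 1 + f_happycat(x), D = 10L,
                 range = c(-100, 100), optimum = 1, minimizer = -1,
                 desc = "Happy Cat analogue (+1)"),
    cec09 = list(f = function(x) 1 + f_ackley(x), D = 10L,
                 range = c(-100, 100), optimum = 1, minimizer = 0,
                 desc = "Ackley analogue (unshifted, +1)"),
    cec10 = list(f = function(x) 1 + f_schaffer_exp(x), D = 10L,
                 range = c(-100, 100), optimum = 1, minimizer = 0,
                 desc = "expanded Schaffer F6 analogue (+1)"),
    sphere = list(f = f_sphere, D = 10L, range = c(-100, 100),
                  optimum = 0, minimizer = 0, free_dim = TRUE,
                  desc = "sphere (raw, minimum 0)"),
    `rastrigin-raw` = list(f = f_rastrigin, D = 10L, range = c(-5.12, 5.12),
                           optimum = 0, minimizer = 0, free_dim = TRUE,
                           desc = "Rastrigin (raw, minimum 0)"),
    `ackley-raw` = list(f = f_ackley, D = 10L, range = c(-32.768, 32.768),
                        optimum = 0, minimizer = 0, free_dim = TRUE,
                        desc = "Ackley (raw, minimum 0)")
  )
}

#' Construct a registered benchmark problem
#'
#' Returns a box-constrained objective with its dimension, search range and
#' known-optimum metadata. The `cec01`--`cec10` entries follow the CEC2019
#' conventions (dimension, range, minimum value 1); `cec04`--`cec10` are
#' unshifted, unrotated analogues of the classic functions, so their values
#' are not comparable with results obtained from the official shifted suite.
#' The elementary problems (`sphere`, `rastrigin-raw`, `ackley-raw`) accept a
#' custom dimension and range.
#'
#' @param name Problem identifier; see [list_problems()].
#' @param dimension Optional dimension override (elementary problems only).
#' @param range Optional length-2 range override (elementary problems only).
#' @return An object of class `opt_problem`: a list with `name`, `bounds`
#'   ([bounds()]), `objective` (function of a numeric vector), `optimum_value`
#'   and `minimizer` (a known global minimizer, or `NULL` when none is
#'   registered).
#' @examples
#' p <- make_benchmark("sphere", dimension = 2, range = c(-5, 5))
#' p$objective(c(1, 2))
#' @export
make_benchmark <- function(name, dimension = NULL, range = NULL) {
  reg <- problem_registry()
  if (length(name) != 1L || !name %in% names(reg)) {
    stop("unknown problem '", paste(name, collapse = ","),
         "'; see list_problems()", call. = FALSE)
  }
  spec <- reg[[name]]
  if ((!is.null(dimension) || !is.null(range)) && !isTRUE(spec$free_dim)) {
    stop("dimension/range overrides are only supported for the elementary ",
         "problems (sphere, rastrigin-raw, ackley-raw)", call. = FALSE)
  }
  D <- if (is.null(dimension)) spec$D else as.integer(dimension)
  rng <- if (is.null(range)) spec$range else as.numeric(range)
  minimizer <- if (is.null(spec$minimizer)) NULL else rep_len(spec$minimizer, D)
  structure(list(
    name = name,
    bounds = bounds(D, rng[1], rng[2]),
    objective = spec$f,
    optimum_value = spec$optimum,
    minimizer = minimizer,
    description = spec$desc
  ), class = "opt_problem")
}

#' List the registered benchmark problems
#'
#' @return A data frame with one row per registered problem: name, dimension,
#'   search range, known optimum value and a short description.
#' @export
list_problems <- function() {
  reg <- problem_registry()
  data.frame(
    name = names(reg),
    dimension = vapply(reg, function(s) s$D, 0L),
    lower = vapply(reg, function(s) s$range[1], 0),
    upper = vapply(reg, function(s) s$range[2], 0),
    optimum = vapply(reg, function(s) s$optimum, 0),
    description = vapply(reg, function(s) s$desc, ""),
    row.names = NULL
  )
}

#' @export
print.opt_problem <- function(x, ...) {
  cat(sprintf("Benchmark problem '%s': %s\n", x$name, x$description))
  cat(sprintf("  D = %d, range [%g, %g], optimum value %g\n",
              x$bounds$dimension, x$bounds$lower[1], x$bounds$upper[1],
              x$optimum_value))
  invisible(x)
}

#' Evaluate a problem objective under budget accounting
#'
#' Every evaluation increments the budget counter by exactly one; evaluating
#' with an exhausted budget is an error. This is the only path through which
#' the optimizers touch an objective, which makes the FFE accounting exact.
#'
#' @param problem An `opt_problem` from [make_benchmark()].
#' @param x Numeric vector within the problem bounds.
#' @param budget Optional [budget_counter()]; `NULL` skips accounting.
#' @return The objective value (a single finite number).
#' @export
evaluate_problem <- function(problem, x, budget = NULL) {
  if (length(x) != problem$bounds$dimension) {
    stop("position has length ", length(x), ", expected ",
         problem$bounds$dimension, call. = FALSE)
  }
  if (!is.null(budget)) {
    if (budget$used >= budget$limit) {
      stop("FFE budget exhausted", call. = FALSE)
    }
    budget$used <- budget$used + 1L
  }
  problem$objective(x)
}

# evaluate a matrix of candidate rows, stopping when the budget runs out;
# returns the fitness values (NA for rows left unevaluated)
evaluate_rows <- function(problem, X, budget) {
  n <- nrow(X)
  fit <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (budget$used >= budget$limit) break
    fit[i] <- evaluate_problem(problem, X[i, ], budget)
  }
  fit
}
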