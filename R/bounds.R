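#' Box constraints for a continuous search space
#'
#' A `bounds` object holds the per-dimension lower and upper limits of a
#' box-constrained search space. Scalars are recycled to the requested
#' dimension, so `bounds(10, -100, 100)` gives the usual symmetric box.
#'
#' @param dimension Positive integer, number of decision variables.
#' @param lower,upper Numeric vectors of length 1 or `dimension`; must satisfy
#'   `lower[j] < upper[j]` for every `j`.
#' @return An object of class `bounds` with elements `dimension`, `lower`,
#'   `upper`.
#' @examples
#' b <- bounds(3, -1, 1)
#' clamp(c(-2, 0, 5), b)
#' @export
bounds <- function(dimension, lower, upper) {
  if (length(dimension) != 1L || !is.finite(dimension) || dimension < 1 ||
      dimension != round(dimension)) {
    stop("'dimension' must be a positive integer", call. = FALSE)
  }
  dimension <- as.integer(dimension)
  lower <- rep_len(as.numeric(lower), dimension)
  upper <- rep_len(as.numeric(upper), dimension)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("each lower bound must be strictly below its upper bound",
         call. = FALSE)
  }
  structure(list(dimension = dimension, lower = lower, upper = upper),
            class = "bounds")
}

#' @export
print.bounds <- function(x, ...) {
  cat("Box bounds: D =", x$dimension, "\n")
  rng <- unique(paste0("[", format(x$lower), ", ", format(x$upper), "]"))
  if (length(rng) == 1L) {
    cat("  range", rng, "in every dimension\n")
  } else {
    cat("  per-dimension ranges:",
        paste(utils::head(rng, 5), collapse = " "), "...\n")
  }
  invisible(x)
}

#' Clamp positions to a box
#'
#' Componentwise projection onto `[lower, upper]`; the out-of-bounds handling
#' used throughout the optimizers.
#'
#' @param x Numeric vector of length `bounds$dimension`, or a matrix with that
#'   many columns (one row per candidate).
#' @param bounds A [bounds()] object.
#' @return `x` with every component forced into the box.
#' @export
clamp <- function(x, bounds) {
  if (is.matrix(x)) {
    x <- pmin(pmax(x, rep(bounds$lower, each = nrow(x))),
              rep(bounds$upper, each = nrow(x)))
  } else {
    x <- pmin(pmax(x, bounds$lower), bounds$upper)
  }
  x
}

# vapply over candidates returns a D x n matrix, except for D = 1 where it
# collapses to a vector; normalize to one candidate per row
rows_from_vapply <- function(v, D) {
  if (is.matrix(v)) t(v) else matrix(v, ncol = D)
}

in_bounds <- function(x, bounds, tol = 0) {
  all(x >= bounds$lower - tol) && all(x <= bounds$upper + tol)
}

#' Fitness-function-evaluation budget counter
#'
#' Budgets in FFE (fitness function evaluations) are the sole termination
#' authority of the optimizers: every call to the objective increments the
#' counter by exactly one and the counter can never exceed its limit.
#'
#' @param limit Positive integer, the maximum number of evaluations (maxFFE).
#' @return An environment of class `budget_counter` with fields `used` and
#'   `limit`.
#' @seealso [budget_used()], [budget_left()], [evaluate_problem()]
#' @export
budget_counter <- function(limit) {
  if (length(limit) != 1L || !is.finite(limit) || limit < 1) {
    stop("'limit' must be a positive integer", call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  e$used <- 0L
  e$limit <- as.integer(limit)
  class(e) <- "budget_counter"
  e
}

#' @rdname budget_counter
#' @param budget A [budget_counter()] object.
#' @export
budget_used <- function(budget) budget$used

#' @rdname budget_counter
#' @export
budget_left <- function(budget) budget$limit - budget$used

#' @export
print.budget_counter <- function(x, ...) {
  cat(sprintf("FFE budget: %d / %d used\n", x$used, x$limit))
  invisible(x)
}
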