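# Nonparametric comparison of optimizers across problems: tied Friedman
# ranks, the Friedman chi-square and Iman-Davenport F refinement, Holm's
# step-down post-hoc procedure against a control method, and an exact
# Wilcoxon signed-rank test.

#' Friedman ranks of a score table
#'
#' Ranks the methods within each problem (row), rank 1 for the best score;
#' tied scores receive the average of the ranks they span. Scores are
#' lower-is-better by default (fitness minimization); set
#' `lower_is_better = FALSE` for accuracy-style tables.
#'
#' @param scores Numeric `n x k` matrix or data frame, problems in rows,
#'   methods in columns.
#' @param lower_is_better Orientation flag, default `TRUE`.
#' @return A list of class `rank_table`: `ranks` (`n x k`),
#'   `average_ranks` (named, length `k`), `n`, `k`. Every rank row and the
#'   average ranks sum to `k (k + 1) / 2`.
#' @examples
#' s <- rbind(p1 = c(a = 3, b = 1, c = 2), p2 = c(2, 2, 5))
#' friedman_ranks(s)$ranks
#' @export
friedman_ranks <- function(scores, lower_is_better = TRUE) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (nrow(scores) < 2 || ncol(scores) < 2) {
    stop("need at least 2 problems and 2 methods", call. = FALSE)
  }
  if (!lower_is_better) scores <- -scores
  ranks <- t(apply(scores, 1, rank, ties.method = "average"))
  dimnames(ranks) <- dimnames(scores)
  structure(list(ranks = ranks,
                 average_ranks = colMeans(ranks),
                 n = nrow(scores), k = ncol(scores)),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("Friedman ranks: %d methods on %d problems\n", x$k, x$n))
  print(round(rbind(x$ranks, average = x$average_ranks), 3))
  invisible(x)
}

#' Friedman chi-square statistic
#'
#' `chi2_r = 12 n / (k (k+1)) * sum_j Rbar_j^2 - 3 n (k + 1)`, computed
#' from the average ranks of `k` methods over `n` problems. Under the null
#' of no method differences it is approximately chi-square with `k - 1`
#' degrees of freedom.
#'
#' @param average_ranks Numeric vector of k average ranks, or a
#'   `rank_table`.
#' @param n Number of problems (ignored when a `rank_table` is given).
#' @return The statistic (a single number).
#' @export
friedman_statistic <- function(average_ranks, n = NULL) {
  if (inherits(average_ranks, "rank_table")) {
    n <- average_ranks$n
    average_ranks <- average_ranks$average_ranks
  }
  if (is.null(n)) stop("'n' (number of problems) is required", call. = FALSE)
  k <- length(average_ranks)
  12 * n / (k * (k + 1)) * sum(average_ranks^2) - 3 * n * (k + 1)
}

#' Iman-Davenport F refinement of the Friedman statistic
#'
#' `F_ID = (n - 1) chi2 / (n (k - 1) - chi2)`, distributed as F with
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom under the null; less
#' conservative than the raw chi-square approximation.
#'
#' @param chi2 The Friedman statistic.
#' @param n Number of problems.
#' @param k Number of methods.
#' @return The F statistic.
#' @export
iman_davenport <- function(chi2, n, k) {
  if (chi2 >= n * (k - 1)) {
    stop("degenerate statistic: chi2 must be below n (k - 1)", call. = FALSE)
  }
  (n - 1) * chi2 / (n * (k - 1) - chi2)
}

#' Critical values for the Friedman and Iman-Davenport tests
#'
#' @param alpha Significance level in (0, 1).
#' @param n Number of problems.
#' @param k Number of methods.
#' @return Named vector: `chi2_crit` (upper-alpha chi-square quantile with
#'   `k - 1` df) and `f_crit` (upper-alpha F quantile with
#'   `(k - 1, (k - 1)(n - 1))` df).
#' @examples
#' critical_values(0.05, n = 10, k = 12)  # ~ 19.7 and 1.89
#' @export
critical_values <- function(alpha, n, k) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  c(chi2_crit = stats::qchisq(1 - alpha, df = k - 1),
    f_crit = stats::qf(1 - alpha, df1 = k - 1, df2 = (k - 1) * (n - 1)))
}

#' Holm's step-down post-hoc procedure against a control method
#'
#' Compares each method with the control using the normal approximation of
#' average-rank differences, `z = (Rbar_j - Rbar_control) /
#' sqrt(k (k+1) / (6 n))`, with one-sided upper-tail p-values by default
#' (the control is hypothesized better, i.e. lower-ranked). P-values are
#' ordered ascending; the i-th (0-based) is compared against
#' `alpha / (m - i)` with `m = k - 1` comparisons, rejecting sequentially
#' until the first failure.
#'
#' @param average_ranks Named numeric vector of average ranks (or a
#'   `rank_table`).
#' @param control Name of the control method.
#' @param n Number of problems.
#' @param alphas Significance levels for the reported thresholds, default
#'   `c(0.05, 0.1)`.
#' @param sided `"one"` (default) or `"two"`.
#' @return A data frame of class `holm_table`, ordered by p-value:
#'   comparison label, `z`, `p`, 0-based `rank`, one threshold column per
#'   alpha, and one logical rejection column per alpha.
#' @export
holm_stepdown <- function(average_ranks, control, n = NULL,
                          alphas = c(0.05, 0.1), sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (inherits(average_ranks, "rank_table")) {
    n <- average_ranks$n
    average_ranks <- average_ranks$average_ranks
  }
  if (is.null(n)) stop("'n' (number of problems) is required", call. = FALSE)
  if (!control %in% names(average_ranks)) {
    stop("control '", control, "' not among the methods", call. = FALSE)
  }
  k <- length(average_ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  others <- setdiff(names(average_ranks), control)
  z <- (average_ranks[others] - average_ranks[[control]]) / se
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (sided == "two") p <- pmin(1, 2 * pmin(p, 1 - p))
  ord <- order(p)
  m <- k - 1
  out <- data.frame(
    comparison = paste(control, "vs", others[ord]),
    z = unname(z[ord]),
    p = unname(p[ord]),
    rank = seq_len(m) - 1L
  )
  for (a in alphas) {
    thr <- a / (m - out$rank)
    out[[paste0("threshold_", a)]] <- thr
    # step-down: reject while p < threshold, stop at the first failure
    ok <- out$p < thr
    first_fail <- match(FALSE, ok, nomatch = m + 1L)
    out[[paste0("reject_", a)]] <- seq_len(m) < first_fail
  }
  class(out) <- c("holm_table", "data.frame")
  out
}

#' Exact Wilcoxon signed-rank test for paired scores
#'
#' Tests paired differences `x - y`. Zero differences are dropped
#' (Wilcoxon's original prescription); tied absolute differences receive
#' average ranks. For `n <= 25` retained pairs the null distribution of the
#' positive-rank sum is computed exactly by enumerating all sign
#' assignments (via a dynamic-programming convolution over the doubled
#' ranks, so tied half-ranks are handled exactly); above that a normal
#' approximation with tie-corrected variance is used.
#'
#' @param x,y Equal-length numeric vectors of paired scores.
#' @param alternative `"greater"` (median of `x - y` positive), `"less"`,
#'   or `"two.sided"`.
#' @param exact_max Largest n for which the exact distribution is
#'   enumerated (default 25).
#' @return List of class `wilcoxon_sr`: `statistic` (positive-rank sum
#'   `V`), `p_value`, `n` (pairs after zero removal), `method` ("exact" or
#'   "normal").
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0), "greater")$p_value  # 1/8
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_max = 25) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; test undefined", call. = FALSE)
  r <- rank(abs(d), ties.method = "average")
  v <- sum(r[d > 0])

  if (n <= exact_max) {
    # exact null distribution over doubled ranks (integers even with ties)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with sum s
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- round(2 * v)
    p_ge <- sum(probs[(v2 + 1L):(total + 1L)])   # P(V >= v)
    p_le <- sum(probs[seq_len(v2 + 1L)])         # P(V <= v)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    # continuity-corrected normal tails
    p_ge <- stats::pnorm((v - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
    p_le <- stats::pnorm((v + 0.5 - mu) / sqrt(sig2))
    method <- "normal"
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(statistic = v, p_value = p, n = n, method = method,
                 alternative = alternative),
            class = "wilcoxon_sr")
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank test (%s, %s): V = %g, n = %d, p = %.4g\n",
              x$method, x$alternative, x$statistic, x$n, x$p_value))
  invisible(x)
}

#' Full rank-based comparison of methods across problems
#'
#' One call running the whole comparison pipeline on a score table:
#' Friedman ranks, the Friedman and Iman-Davenport statistics with their
#' p-values and critical values, and Holm's step-down procedure against a
#' control method (by default the method with the best average rank).
#'
#' @param scores `n x k` score matrix (problems x methods), lower is
#'   better unless `lower_is_better = FALSE`.
#' @param control Control method for the post-hoc tests; default the
#'   best-ranked method.
#' @param alpha Significance level for the critical values, default 0.05.
#' @param alphas Thresholds reported in the Holm table.
#' @param lower_is_better Score orientation.
#' @param sided Sidedness of the Holm p-values.
#' @return A list of class `method_comparison` with `ranks`
#'   (a `rank_table`), `friedman`, `iman_davenport`, p-values, critical
#'   values, `holm` (a `holm_table`) and `control`.
#' @examples
#' path <- system.file("extdata", "cec2019_mean_fitness.csv",
#'                     package = "coffo")
#' compare_methods(read.csv(path, row.names = 1))
#' @export
compare_methods <- function(scores, control = NULL, alpha = 0.05,
                            alphas = c(0.05, 0.1), lower_is_better = TRUE,
                            sided = c("one", "two")) {
  rt <- friedman_ranks(scores, lower_is_better = lower_is_better)
  if (is.null(control)) control <- names(which.min(rt$average_ranks))
  chi2 <- friedman_statistic(rt)
  fid <- iman_davenport(chi2, rt$n, rt$k)
  crit <- critical_values(alpha, rt$n, rt$k)
  structure(list(
    ranks = rt,
    control = control,
    friedman = chi2,
    friedman_p = stats::pchisq(chi2, df = rt$k - 1, lower.tail = FALSE),
    iman_davenport = fid,
    iman_davenport_p = stats::pf(fid, rt$k - 1, (rt$k - 1) * (rt$n - 1),
                                 lower.tail = FALSE),
    critical = crit,
    alpha = alpha,
    holm = holm_stepdown(rt, control, alphas = alphas, sided = sided)
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, digits = 4, ...) {
  rt <- x$ranks
  cat(sprintf("Rank comparison of %d methods on %d problems\n", rt$k, rt$n))
  cat("\nAverage ranks:\n")
  print(round(sort(rt$average_ranks), 2))
  cat(sprintf("\nFriedman chi2 = %.4g (critical %.4g at alpha = %g), p = %.3g\n",
              x$friedman, x$critical[["chi2_crit"]], x$alpha, x$friedman_p))
  cat(sprintf("Iman-Davenport F = %.4g (critical %.4g), p = %.3g\n",
              x$iman_davenport, x$critical[["f_crit"]], x$iman_davenport_p))
  cat(sprintf("\nHolm step-down against control '%s':\n", x$control))
  h <- x$holm
  h$z <- round(h$z, 3)
  h$p <- signif(h$p, 3)
  for (cn in grep("^threshold_", names(h), value = TRUE)) {
    h[[cn]] <- signif(h[[cn]], 4)
  }
  print(h, row.names = FALSE)
  invisible(x)
}
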