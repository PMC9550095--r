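test_that("row ranks handle ties by midrank and conserve the rank sum", {
  s <- rbind(p1 = c(A = 3, B = 1, C = 2),
             p2 = c(A = 5, B = 5, C = 5),
             p3 = c(A = 1, B = 2, C = 3))
  rt <- friedman_ranks(s)
  expect_equal(unname(rt$ranks["p1", ]), c(3, 1, 2))
  expect_equal(unname(rt$ranks["p2", ]), c(2, 2, 2))
  expect_equal(unname(rt$ranks["p3", ]), c(1, 2, 3))
  expect_true(all(rowSums(rt$ranks) == 6))  # k(k+1)/2
  expect_equal(sum(rt$average_ranks), 6)
  # invariance under strictly monotone transforms of the scores
  expect_equal(friedman_ranks(exp(s))$ranks, rt$ranks)
  # orientation flag for higher-is-better tables
  expect_equal(unname(friedman_ranks(s, lower_is_better = FALSE)$ranks["p3", ]),
               c(3, 2, 1))
  expect_error(friedman_ranks(rbind(c(1, NA), c(1, 2))), "finite")
})

test_that("friedman statistic: hand-derived case, null case, base-R oracle", {
  # two rows both ranked (1,2,3): chi2 = 12*2/(3*4)*(1+4+9) - 3*2*4 = 4
  expect_equal(friedman_statistic(c(1, 2, 3), n = 2), 4)
  expect_equal(friedman_statistic(c(2, 2, 2), n = 5), 0)
  # agreement with stats::friedman.test on a tie-free table
  y <- coffo:::with_seed(8, matrix(rnorm(40), 8, 5))
  ft <- stats::friedman.test(y)
  expect_equal(friedman_statistic(friedman_ranks(y)),
               unname(ft$statistic))
})

test_that("iman-davenport transformation and critical values", {
  expect_equal(iman_davenport(30, 10, 12), 3.375)
  expect_equal(iman_davenport(0, 10, 12), 0)
  expect_error(iman_davenport(111, 10, 12), "degenerate")
  cv10 <- critical_values(0.05, 10, 12)
  expect_equal(unname(cv10["chi2_crit"]), qchisq(0.95, 11))
  expect_equal(unname(cv10["f_crit"]), qf(0.95, 11, 99))
  # chi-square critical value increases with the number of methods
  expect_gt(critical_values(0.05, 10, 15)["chi2_crit"],
            cv10["chi2_crit"])
})

test_that("holm step-down orders, thresholds, and stops correctly", {
  # equal ranks: all z = 0, p = 0.5, nothing rejected
  ar <- setNames(rep(5, 4), c("ctl", "m1", "m2", "m3"))
  h0 <- holm_stepdown(ar, "ctl", n = 10)
  expect_true(all(h0$p == 0.5))
  expect_false(any(h0$reject_0.05))
  # thresholds follow alpha / (m - i)
  expect_equal(h0$threshold_0.05, 0.05 / (3 - h0$rank))
  # step-down stops at the first failure even if later p dip below
  ar2 <- setNames(c(1, 4, 2.05, 6), c("ctl", "m1", "m2", "m3"))
  h2 <- holm_stepdown(ar2, "ctl", n = 8)
  expect_equal(h2$comparison[1], "ctl vs m3")
  first_fail <- match(FALSE, h2$p < h2$threshold_0.05)
  if (!is.na(first_fail) && first_fail < nrow(h2)) {
    expect_false(any(h2$reject_0.05[first_fail:nrow(h2)]))
  }
  expect_error(holm_stepdown(ar, "nope", n = 10), "not among")
})

test_that("wilcoxon exact tail by enumeration and against base R", {
  # three positive differences: only 1 of 2^3 sign patterns reaches V = 6
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0),
                                    "greater")$p_value, 1 / 8)
  # uniformly-signed differences at n = 21 hit the 2^-21 floor
  w21 <- wilcoxon_signed_rank(21:1, rep(0, 21), "greater")
  expect_equal(w21$p_value, 2^-21)
  expect_equal(w21$statistic, 21 * 22 / 2)
  # tie-free agreement with stats::wilcox.test exact p-values
  coffo:::with_seed(14, {
    for (i in 1:20) {
      x <- rnorm(12)
      y <- rnorm(12)
      for (alt in c("two.sided", "greater", "less")) {
        ours <- wilcoxon_signed_rank(x, y, alt)$p_value
        ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                                  alternative = alt)$p.value
        expect_equal(ours, ref, tolerance = 1e-12)
      }
    }
  })
  # tied absolute differences still give a proper distribution
  wt <- wilcoxon_signed_rank(c(2, 2, 3, -2, 4, 5), rep(0, 6), "greater")
  expect_true(wt$p_value > 0 && wt$p_value < 1)
  expect_error(wilcoxon_signed_rank(c(1, 1), c(1, 1)), "all differences")
})

test_that("normal approximation tracks the exact mid-range tail", {
  coffo:::with_seed(21, {
    x <- rnorm(20, 0.3)
    y <- rnorm(20)
  })
  pe <- wilcoxon_signed_rank(x, y, "greater")$p_value
  pn <- wilcoxon_signed_rank(x, y, "greater", exact_max = 0)$p_value
  expect_lt(abs(pn - pe) / pe, 0.1)
})

test_that("under the null the one-sided p is not systematically extreme", {
  ps <- coffo:::with_seed(33, vapply(1:40, function(i) {
    a <- rnorm(30)
    b <- rnorm(30)
    wilcoxon_signed_rank(a, b, "greater")$p_value
  }, 0))
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(min(ps), 1e-4)
})

test_that("compare_methods assembles the whole pipeline consistently", {
  y <- coffo:::with_seed(5, matrix(rnorm(60), 10, 6,
    dimnames = list(paste0("p", 1:10), paste0("m", 1:6))))
  y[, 6] <- y[, 6] - 3  # make m6 the clear control
  cm <- compare_methods(y)
  expect_equal(cm$control, "m6")
  expect_equal(cm$friedman, friedman_statistic(cm$ranks))
  expect_equal(cm$iman_davenport,
               iman_davenport(cm$friedman, 10, 6))
  expect_equal(nrow(cm$holm), 5)
  expect_output(print(cm), "Holm step-down")
})
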