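test_that("opposite_point follows the mirror formula and is an involution", {
  b <- bounds(1, 0, 10)
  expect_equal(opposite_point(3, b), 7)
  expect_equal(opposite_point(5, b), 5)  # midpoint is the fixed point
  expect_error(opposite_point(11, b), "within bounds")
  coffo:::with_seed(7, {
    for (i in 1:200) {
      lo <- runif(3, -50, 0)
      hi <- lo + runif(3, 0.1, 100)
      bb <- bounds(3, lo, hi)
      x <- runif(3, lo, hi)
      expect_equal(opposite_point(opposite_point(x, bb), bb), x)
    }
  })
})

test_that("logistic map arithmetic, fixed point, and range closure", {
  expect_equal(logistic_step(0.3), 0.84)
  expect_equal(logistic_step(0.75), 0.75)
  expect_error(logistic_step(0), "open interval")
  expect_error(logistic_step(1.2), "open interval")
  # orbits from admissible seeds stay in (0,1) for the K <= 4 steps used
  coffo:::with_seed(11, {
    for (i in 1:500) {
      beta <- coffo:::draw_beta0(1)
      for (k in 1:4) {
        beta <- logistic_step(beta)
        expect_true(beta >= 0 && beta <= 1)
      }
    }
  })
})

test_that("chaotic variants interpolate as documented", {
  b <- bounds(2, -4, 4)
  expect_equal(chaotic_variant(c(2, -3), c(0.5, 0.5), b, "literal"),
               c(1, -1.5))
  # beta -> 1 recovers x in both modes
  expect_equal(chaotic_variant(c(2, -3), 1 - 1e-12, b, "literal"),
               c(2, -3), tolerance = 1e-9)
  expect_equal(chaotic_variant(c(2, -3), 1 - 1e-12, b, "normalized"),
               c(2, -3), tolerance = 1e-9)
  # the lower bound is the anchor of normalized mode
  expect_equal(chaotic_variant(c(-4, -4), c(0.3, 0.9), b, "normalized"),
               c(-4, -4))
  expect_error(chaotic_variant(c(0, 0), c(0, 0.5), b), "in \\(0, 1\\)")
})

test_that("chaotic-opposition init equals brute force over the candidate union", {
  p <- tiny_sphere(1, c(-1, 1))
  # replay the generator's stream to rebuild the 8 candidates independently
  seed <- 99
  cand <- coffo:::with_seed(seed, {
    P <- matrix(runif(4, -1, 1), 4, 1)
    Po <- -P[1:2, , drop = FALSE]          # opposite in a symmetric box
    Pc <- rbind(coffo:::draw_beta0(1) * P[3, ],
                coffo:::draw_beta0(1) * P[4, ])
    rbind(P, Po, Pc)
  })
  got <- coffo:::with_seed(seed, {
    chaotic_opposition_init(p, 4, budget_counter(8))
  })
  fit_all <- cand[, 1]^2
  keep <- order(fit_all)[1:4]
  expect_equal(sort(got$positions[, 1]), sort(cand[keep, 1]))
  expect_equal(got$fitness, sort(fit_all)[1:4])
  expect_equal(got$random_best, min(fit_all[1:4]))
})

test_that("initialization spends exactly 2N FFEs and dominates its random half", {
  p <- make_benchmark("sphere")
  for (s in 1:20) {
    bud <- budget_counter(1000)
    r <- coffo:::with_seed(s, chaotic_opposition_init(p, 20, bud))
    expect_identical(budget_used(bud), 40L)
    expect_equal(nrow(r$positions), 20L)
    expect_lte(r$fitness[1], r$random_best)
  }
  expect_error(coffo:::with_seed(1,
    chaotic_opposition_init(p, 5, budget_counter(100))), "even")
})

test_that("shrinkage follows the budget schedule", {
  expect_equal(shrinkage(1, 25050), 1)
  expect_equal(shrinkage(25050, 25050), 1 / 25050)
  expect_equal(shrinkage(12526, 25050), 0.5)
  expect_error(shrinkage(0, 10), "must lie")
  # strictly decreasing, bounded in (0, 1]
  lam <- shrinkage(1:1000, 1000)
  expect_true(all(diff(lam) < 0))
  expect_true(all(lam > 0 & lam <= 1))
})

test_that("chaotic local search hand-iterated chain on a 1-D quadratic", {
  p <- structure(list(name = "quad", bounds = bounds(1, 0, 1),
                      objective = function(x) x^2,
                      optimum_value = 0, minimizer = 0),
                 class = "opt_problem")
  seed <- 5
  # with lambda = 1, candidates equal S = beta_k on [0,1]; the first k with
  # beta_k^2 < 0.64 must be returned
  chain <- coffo:::with_seed(seed, {
    beta <- coffo:::draw_beta0(1)
    sapply(1:10, function(k) beta <<- logistic_step(beta))
  })
  win <- which(chain^2 < 0.64)[1]
  expect_false(is.na(win))
  bud <- budget_counter(100)
  res <- coffo:::with_seed(seed, chaotic_local_search(
    list(position = 0.8, fitness = 0.64), p, k_steps = 10,
    lambda = 1, budget = bud))
  expect_true(res$improved)
  expect_equal(res$position, chain[win])
  expect_identical(budget_used(bud), as.integer(win))
})

test_that("chaotic local search never worsens the incumbent (fuzz)", {
  p <- tiny_sphere(3)
  coffo:::with_seed(123, {
    for (i in 1:200) {
      pos <- runif(3, -5, 5)
      best <- list(position = pos, fitness = p$objective(pos))
      lam <- runif(1)
      res <- chaotic_local_search(best, p, k_steps = sample(1:4, 1),
                                  lambda = lam, budget = budget_counter(10))
      expect_lte(res$fitness, best$fitness)
      if (!res$improved) expect_identical(res$position, best$position)
    }
  })
})
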