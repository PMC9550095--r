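test_that("uniform initialization fills the box with the right marginals", {
  b <- bounds(3, -1, 1)
  P <- coffo:::with_seed(1, init_random_population(b, 1000))
  expect_true(all(P >= -1 & P <= 1))
  expect_true(all(abs(colMeans(P)) < 0.1))  # law of large numbers
  expect_error(init_random_population(b, 0), ">= 1")
  # determinism
  expect_identical(coffo:::with_seed(3, init_random_population(b, 10)),
                   coffo:::with_seed(3, init_random_population(b, 10)))
})

test_that("osphresis step is a clamped signed-uniform walk", {
  b <- bounds(2, -100, 100)
  cur <- c(10, -10)
  expect_equal(coffo:::with_seed(1, osphresis_step(cur, b, step_scale = 0)),
               cur)
  # clamping at the lower corner
  b2 <- bounds(2, 0, 1)
  low <- coffo:::with_seed(2, replicate(50, osphresis_step(c(0, 0), b2, 1)))
  expect_true(all(low >= 0))
  # empirical step distribution is uniform on [-1, 1]
  b1 <- bounds(1, -100, 100)
  draws <- coffo:::with_seed(4, vapply(1:10000, function(i) {
    osphresis_step(0, b1, 1)
  }, 0))
  ks <- suppressWarnings(stats::ks.test(draws, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("vision phase relocates the swarm only on improvement", {
  pos <- matrix(1:6, 3, 2)
  expect_identical(vision_update(pos, c(9, 9), improved = FALSE), pos)
  moved <- vision_update(pos, c(9, 9), improved = TRUE)
  expect_true(all(moved[, 1] == 9 & moved[, 2] == 9))
})

test_that("both drivers keep exact budgets, monotone traces, bounds closure", {
  for (algo in c("ffo", "coffo")) {
    runner <- if (algo == "ffo") run_ffo else run_coffo
    for (s in 1:4) {
      cp <- counted_problem(make_benchmark("rastrigin-raw", dimension = 3))
      r <- runner(cp$problem, quick_config(seed = s))
      expect_identical(cp$env$n, r$ffes_used)       # no hidden evaluations
      expect_identical(r$ffes_used, 150L)           # budget fully used
      expect_false(cp$env$violated)                 # bounds closure
      expect_true(all(diff(r$trace$best) <= 0))     # monotone best-so-far
      expect_equal(r$best_fitness, min(r$trace$best))
    }
  }
})

test_that("identical seeds give identical results, different seeds differ", {
  p <- tiny_sphere()
  a <- run_coffo(p, quick_config(seed = 7))
  b <- run_coffo(p, quick_config(seed = 7))
  expect_identical(a[c("best_position", "best_fitness", "trace")],
                   b[c("best_position", "best_fitness", "trace")])
  d <- run_coffo(p, quick_config(seed = 8))
  expect_false(identical(a$best_fitness, d$best_fitness))
})

test_that("final best never exceeds the best initial member", {
  p <- tiny_sphere(1, c(-1, 1))
  r <- run_ffo(p, quick_config(seed = 2, max_ffes = 200))
  expect_lte(r$best_fitness, r$trace$best[1])
})

test_that("degenerate configurations are rejected", {
  p <- tiny_sphere()
  expect_error(run_ffo(p, quick_config(seed = 1, max_ffes = 5)),
               "smaller than")
  expect_error(run_coffo(p, quick_config(seed = 1, max_ffes = 15)),
               "smaller than")
  expect_error(optimizer_config(pop_size = 10, max_ffes = 100,
                                cls_trigger = 200), "cannot exceed")
})

test_that("coffo with the trigger at the budget behaves as FFO after its init", {
  # cls_trigger = max_ffes means the local search never runs; the search
  # phase must then consume exactly the same stream as plain FFO
  p <- tiny_sphere()
  cfg <- quick_config(seed = 5, max_ffes = 200, cls_trigger = 200)
  r <- run_coffo(p, cfg)
  expect_identical(r$ffes_used, 200L)
  expect_true(all(diff(r$trace$best) <= 0))
})

test_that("chaotic-opposition start dominates the plain random start", {
  p <- make_benchmark("sphere")
  cmp <- vapply(1:20, function(s) {
    r <- run_coffo(p, optimizer_config(pop_size = 50, max_ffes = 150,
                                       seed = s))
    c(init_best = r$trace$best[1], random_best = r$init_random_best)
  }, c(0, 0))
  expect_true(all(cmp["init_best", ] <= cmp["random_best", ]))
})
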