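test_that("transfer functions match their closed forms and are even", {
  expect_equal(transfer_v("V2", 0), 0)
  expect_equal(transfer_v("V3", 1), 1 / sqrt(2))
  expect_equal(transfer_v("V2", 3), tanh(3))
  expect_equal(transfer_v("V4", 1e8), 1, tolerance = 1e-7)
  x <- seq(-4, 4, by = 0.5)
  for (tf in c("V1", "V2", "V3", "V4")) {
    expect_equal(transfer_v(tf, x), transfer_v(tf, -x), label = tf)
    expect_true(all(transfer_v(tf, x) >= 0 & transfer_v(tf, x) < 1),
                label = tf)
  }
  # V1 against the error function via its normal-CDF identity
  expect_equal(transfer_v("V1", 0.7),
               abs(2 * pnorm(sqrt(pi) / 2 * 0.7 * sqrt(2)) - 1))
  expect_error(transfer_v("V9", 1), "arg")
  expect_error(transfer_v("V1", Inf), "finite")
})

test_that("binarize_step reproduces the seeded flip stream", {
  bits <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  vals <- rep(3, 5)
  got <- coffo:::with_seed(31, binarize_step(bits, vals, "V2"))
  want <- coffo:::with_seed(31, {
    flips <- runif(5) < tanh(3)
    xor(bits, flips)
  })
  expect_identical(got, want)  # tanh(3) ~ 0.995: essentially all flip
  # zero displacement never flips
  expect_identical(coffo:::with_seed(1, binarize_step(bits, rep(0, 5))),
                   bits)
  # repair: an all-off outcome gets one random bit back
  res <- coffo:::with_seed(2, binarize_step(c(TRUE, TRUE), c(50, 50), "V2"))
  expect_true(any(res))
})

test_that("fitness arithmetic and monotonicity follow the weighted form", {
  expect_equal(fs_fitness(0, 10, 10, alpha = 0.99), 0.01)
  expect_equal(fs_fitness(0.1, 5, 10, alpha = 0.99), 0.104)
  expect_error(fs_fitness(0.1, 0, 10), ">= 1")
  expect_gt(fs_fitness(0.2, 5, 10, 0.5), fs_fitness(0.1, 5, 10, 0.5))
  expect_gt(fs_fitness(0.1, 6, 10, 0.5), fs_fitness(0.1, 5, 10, 0.5))
})

test_that("selection ratio is the popcount fraction", {
  expect_equal(selection_ratio(c(rep(1, 2), rep(0, 13))), 2 / 15)
  expect_equal(selection_ratio(rep(TRUE, 7)), 1)
  expect_equal(selection_ratio(c(1, rep(0, 8))), 1 / 9)
  expect_error(selection_ratio(rep(0, 4)), "at least one")
})

test_that("stratified folds balance class proportions within one sample", {
  y <- factor(rep(c("a", "b", "c"), times = c(40, 25, 15)))
  fold <- stratified_folds(y, 5, seed = 3)
  tab <- table(fold, y)
  for (cl in colnames(tab)) {
    expect_lte(diff(range(tab[, cl])), 1)
  }
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(3, 40))), 5),
               "at least as many")
})

test_that("knn error separates the separable and matches the null rate", {
  sep <- well_separated_data()
  xs <- coffo:::scale_minmax(sep$x)
  expect_equal(knn_error(xs, sep$y, rep(TRUE, 4), n_folds = 5), 0)
  expect_equal(knn_error(xs, sep$y, c(TRUE, FALSE, FALSE, FALSE),
                         n_folds = 5), 0)
  # label-independent features: error approaches 1 - max prior
  coffo:::with_seed(9, {
    x0 <- matrix(rnorm(400 * 3), 400, 3)
    y0 <- factor(rbinom(400, 1, 0.5))
  })
  er <- knn_error(coffo:::scale_minmax(x0), y0, rep(TRUE, 3), fold_seed = 2)
  expect_gt(er, 0.35)
  # determinism for a fixed fold seed
  expect_identical(knn_error(xs, sep$y, rep(TRUE, 4), n_folds = 5,
                             fold_seed = 17),
                   knn_error(xs, sep$y, rep(TRUE, 4), n_folds = 5,
                             fold_seed = 17))
})

test_that("coffo_select returns a coherent fit on planted data", {
  d <- generate_classification(n_samples = 80, n_features = 10,
                               n_informative = 2, effect_size = 3, seed = 2)
  fit <- coffo_select(d$features, d$labels, runs = 3, max_iter = 20,
                      folds = 5, seed = 4)
  expect_s3_class(fit, "coffo_fs")
  expect_gte(fit$mean_fitness, fit$best_fitness)
  expect_true(any(fit$selected))
  expect_equal(fit$selection_ratio, sum(fit$selected) / 10)
  expect_equal(fit$accuracy, 1 - fit$error_rate)
  expect_true(all(diff(fit$trace$best) <= 0))
  expect_true(all(fit$runs$ffes_used == ffe_budget(10, 20)))
  # beats the all-features mask on its own fitness
  xs <- coffo:::scale_minmax(d$features)
  er_all <- knn_error(xs, d$labels, rep(TRUE, 10), n_folds = 5,
                      fold_seed = coffo:::substream_seed(4, "folds"))
  expect_lt(fit$best_fitness, fs_fitness(er_all, 10, 10, 0.99))
  # reproducible end to end
  fit2 <- coffo_select(d$features, d$labels, runs = 3, max_iter = 20,
                       folds = 5, seed = 4)
  expect_identical(fit$selected, fit2$selected)
  expect_identical(fit$runs, fit2$runs)
})

test_that("formula interface, coef, and predict work together", {
  d <- generate_classification(n_samples = 60, n_features = 6,
                               n_informative = 2, effect_size = 4, seed = 3)
  df <- data.frame(d$features, class = d$labels)
  fit <- coffo_select(class ~ ., data = df, runs = 2, max_iter = 15,
                      folds = 5, seed = 9)
  expect_named(coef(fit), colnames(d$features))
  expect_true(sum(coef(fit)) >= 1)
  pr <- predict(fit, d$features)
  expect_s3_class(pr, "factor")
  expect_length(pr, 60)
  # resubstitution accuracy on well-separated planted data is high
  expect_gt(mean(pr == d$labels), 0.9)
})

test_that("ffo variant runs under the same surface", {
  d <- generate_classification(n_samples = 60, n_features = 6,
                               n_informative = 2, effect_size = 4, seed = 6)
  fit <- coffo_select(d$features, d$labels, algorithm = "ffo", runs = 2,
                      max_iter = 15, folds = 5, seed = 2)
  expect_s3_class(fit, "coffo_fs")
  expect_true(all(diff(fit$trace$best) <= 0))
})
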