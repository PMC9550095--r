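# shared fixtures: tiny problems and fast optimizer settings

tiny_sphere <- function(D = 2, range = c(-5, 5)) {
  make_benchmark("sphere", dimension = D, range = range)
}

quick_config <- function(seed, max_ffes = 150, pop_size = 10, ...) {
  optimizer_config(pop_size = pop_size, max_ffes = max_ffes, seed = seed, ...)
}

# wrap a problem so every objective call is counted and bounds violations
# are recorded; used to verify the FFE accounting from outside
counted_problem <- function(p) {
  env <- new.env()
  env$n <- 0L
  env$violated <- FALSE
  obj <- p$objective
  b <- p$bounds
  p$objective <- function(x) {
    env$n <- env$n + 1L
    if (any(x < b$lower - 1e-12) || any(x > b$upper + 1e-12)) {
      env$violated <- TRUE
    }
    obj(x)
  }
  list(problem = p, env = env)
}

well_separated_data <- function(n_per_class = 30, d = 4, gap = 50, seed = 1) {
  coffo:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
               matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
    list(x = x, y = factor(rep(c("a", "b"), each = n_per_class)))
  })
}
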