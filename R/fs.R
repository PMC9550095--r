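# Wrapper feature selection: binary COFFO/FFO over feature masks with a
# cross-validated KNN error fitness. `coffo_select()` is the front-end
# fitting function; everything else is the search machinery behind it.

# one binary swarm run; returns best mask/fitness and the best-so-far trace
#
# Binary adaptation choices (see the methods vignette for the rationale):
# * initial masks are sparse: each member draws a subset density uniformly in
#   (0, init_density] and thresholds its companion position, because good
#   wrapper subsets are small and growing a sparse mask is far easier for the
#   search than pruning a dense one;
# * opposition acts on companions; with the mirrored threshold the opposite
#   member selects a disjoint subset of the same size (opposition in feature
#   choice, not in subset size);
# * the transfer function receives the companion displacement, scaled per bit
#   so that a candidate flips on average about one selected and one
#   unselected feature whatever the current subset size;
# * a candidate identical to its parent flips one random bit instead, so no
#   evaluation is spent re-scoring the incumbent.
run_binary_swarm <- function(xs, y, algorithm, tf, alpha, N, max_ffes,
                             cls_steps, cls_trigger, cbox, step_scale,
                             init_density, k, n_folds, run_seed) {
  O <- ncol(xs)
  fold_assign <- stratified_folds(y, n_folds,
                                  seed = substream_seed(run_seed, "folds"))
  cache <- new.env(parent = emptyenv())
  budget <- budget_counter(max_ffes)

  mask_error <- function(bits) {
    key <- paste(as.integer(bits), collapse = "")
    er <- cache[[key]]
    if (is.null(er)) {
      er <- knn_error(xs, y, bits, k = k, folds = fold_assign)
      cache[[key]] <- er
    }
    er
  }
  eval_mask <- function(bits) {
    budget$used <- budget$used + 1L  # every fitness evaluation costs 1 FFE
    fs_fitness(mask_error(bits), sum(bits), O, alpha)
  }

  # size-balanced displacement scaling: expected flips ~1 within the
  # selected set and ~1 within its complement
  balance_displacement <- function(u, bits) {
    ns <- sum(bits)
    w <- ifelse(bits, O / (2 * max(ns, 1L)), O / (2 * max(O - ns, 1L)))
    u * w
  }
  perturb <- function(bits, u) {
    cand <- binarize_step(bits, balance_displacement(u, bits), tf)
    if (all(cand == bits)) {  # spend the evaluation on a real neighbour
      j <- sample.int(O, 1L)
      cand[j] <- !cand[j]
      cand <- repair_mask(cand)
    }
    cand
  }

  cb <- bounds(O, -cbox, cbox)

  init <- with_seed(substream_seed(run_seed, "init"), {
    dens <- stats::runif(N, 0, init_density)
    q <- cbox * (1 - 2 * dens)  # P(c > q) = dens for c ~ U(-cbox, cbox)
    C <- init_random_population(cb, N)
    Ball <- C > q
    Call <- C
    if (algorithm == "coffo") {
      half <- N %/% 2L
      Co <- opposite_point(C[seq_len(half), , drop = FALSE], cb)
      # mirrored threshold: same density, disjoint feature choice
      bo <- Co > q[seq_len(half)]
      Cc <- rows_from_vapply(vapply((half + 1L):N, function(i) {
        chaotic_variant(C[i, ], draw_beta0(O), cb, mode = "normalized")
      }, numeric(O)), O)
      bc <- Cc > q[(half + 1L):N]
      Call <- rbind(C, Co, Cc)
      Ball <- rbind(Ball, bo, bc)
    }
    Ball <- matrix(apply(Ball, 1, repair_mask), ncol = O, byrow = TRUE)
    fit <- apply(Ball, 1, eval_mask)
    ord <- order(fit)[seq_len(N)]
    list(C = Call[ord, , drop = FALSE], B = Ball[ord, , drop = FALSE],
         fit = fit[ord])
  })

  best <- list(c = init$C[1, ], bits = init$B[1, ], fit = init$fit[1])
  memb_c <- init$C
  memb_b <- init$B
  trace_ffe <- budget$used
  trace_fit <- best$fit

  with_seed(substream_seed(run_seed, "search"), {
    while (budget_left(budget) > 0) {
      m <- min(N, budget_left(budget))
      improved <- FALSE
      for (i in seq_len(m)) {
        u <- stats::runif(O, -step_scale, step_scale)
        c_cand <- clamp(memb_c[i, ] + u, cb)
        b_cand <- perturb(memb_b[i, ], u)
        f <- eval_mask(b_cand)
        if (f < best$fit) {
          best <- list(c = c_cand, bits = b_cand, fit = f)
          improved <- TRUE
          trace_ffe <- c(trace_ffe, budget$used)
          trace_fit <- c(trace_fit, f)
        }
      }
      if (improved) {
        memb_c <- matrix(best$c, N, O, byrow = TRUE)
        memb_b <- matrix(best$bits, N, O, byrow = TRUE)
      }

      if (algorithm == "coffo" && budget$used > cls_trigger &&
          budget_left(budget) > 0) {
        lambda <- shrinkage(budget$used, max_ffes)
        beta <- draw_beta0(O)
        for (kk in seq_len(cls_steps)) {
          if (budget_left(budget) <= 0) break
          beta <- logistic_step(beta)
          S <- -cbox + beta * (2 * cbox)
          c_cand <- (1 - lambda) * best$c + lambda * S
          # rescale the whole-box CLS displacement to the osphresis step
          # scale before binarization
          disp <- step_scale * (c_cand - best$c) / cbox
          b_cand <- perturb(best$bits, disp)
          f <- eval_mask(b_cand)
          if (f < best$fit) {
            best <- list(c = c_cand, bits = b_cand, fit = f)
            memb_c <- matrix(best$c, N, O, byrow = TRUE)
            memb_b <- matrix(best$bits, N, O, byrow = TRUE)
            trace_ffe <- c(trace_ffe, budget$used)
            trace_fit <- c(trace_fit, f)
            break
          }
        }
      }
    }
  })

  list(bits = best$bits, fitness = best$fit,
       error = mask_error(best$bits),
       trace = data.frame(ffe = c(trace_ffe, budget$used),
                          best = c(trace_fit, best$fit)),
       ffes_used = budget$used)
}

#' Wrapper feature selection by binary COFFO/FFO
#'
#' Selects a feature subset for classification by minimizing the wrapper
#' fitness `alpha * ER + (1 - alpha) * |S|/|O|`, where `ER` is the
#' stratified cross-validated error of a KNN classifier restricted to the
#' candidate subset ([knn_error()], [fs_fitness()]). The search runs a
#' binary variant of the chaotic oppositional fruit fly optimizer: each
#' candidate mask is generated from the incumbent by flipping bits with
#' probabilities given by a V-shaped transfer function of the continuous
#' companion displacement ([binarize_step()]); COFFO additionally uses the
#' opposition-based initialization and the budget-shrinking chaotic local
#' search. The whole procedure is repeated over independent runs and the
#' best run's mask is reported.
#'
#' @param x Numeric feature matrix (samples in rows), a data frame of
#'   numeric columns, or a formula.
#' @param y Class labels (any vector coercible to factor).
#' @param data,... For the formula method, the data frame holding the
#'   variables; further arguments passed on.
#' @param algorithm `"coffo"` (default) or `"ffo"` (plain random
#'   initialization, no chaotic local search; both spend the same FFE
#'   budget).
#' @param transfer V-shaped transfer function, one of `"V1"`..`"V4"`
#'   (default `"V2"`, `|tanh|`).
#' @param alpha Error weight of the fitness, default 0.99.
#' @param pop_size Swarm size, default 10.
#' @param max_iter Iteration schedule used to derive the default budget
#'   `ffe_budget(pop_size, max_iter)` (default 100, i.e. 1,010 FFEs).
#' @param max_ffes Explicit FFE budget overriding the schedule.
#' @param runs Number of independent optimization runs, default 20.
#' @param k KNN neighbourhood size, default 5.
#' @param folds Cross-validation folds, default 10.
#' @param cls_steps Chaotic-local-search steps per trigger, default 4.
#' @param cls_trigger FFE count enabling the chaotic local search, default
#'   `floor(max_ffes / 3)`.
#' @param companion_box Half-width of the continuous companion space,
#'   default 4 (spans the effective range of all four transfer functions).
#' @param step_scale Osphresis step half-width in companion space; the
#'   default `4 / n_features` targets an expected candidate Hamming
#'   distance of about two bits.
#' @param init_density Upper bound of the per-member uniform draw of the
#'   initial subset density (default 0.2): initial masks are sparse because
#'   informative wrapper subsets are small and growing a mask under the
#'   fitness is far more reliable than pruning a dense one.
#' @param scale Min-max scale the features to `[0, 1]` before KNN (default
#'   `TRUE`; Euclidean KNN is scale-sensitive).
#' @param seed Root seed; every run derives its own substreams from it.
#' @return An object of class `coffo_fs` with, among others:
#'   `selected` (named logical mask of the best run), `best_fitness`,
#'   `accuracy` and `error_rate` of the selected mask under the CV
#'   protocol, `selection_ratio`, `runs` (per-run summary data frame),
#'   `frequency` (per-feature selection frequency across runs), and
#'   `trace` (best run's best-so-far fitness trace). Methods:
#'   [print.coffo_fs()], `summary`, `coef` (the 0/1 mask), `predict`
#'   (KNN on the selected features), `plot`.
#' @examples
#' d <- generate_classification(n_samples = 60, n_features = 8,
#'                              n_informative = 2, effect_size = 3, seed = 1)
#' fit <- coffo_select(d$features, d$labels, runs = 2, max_iter = 10,
#'                     folds = 5, seed = 1)
#' fit
#' @export
coffo_select <- function(x, ...) UseMethod("coffo_select")

#' @rdname coffo_select
#' @param formula A formula `class ~ .` or `class ~ f1 + f2 + ...`.
#' @export
coffo_select.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1, drop = FALSE]
  res <- coffo_select.default(x, y, ...)
  res$call <- match.call()
  res
}

#' @rdname coffo_select
#' @export
coffo_select.default <- function(x, y, algorithm = c("coffo", "ffo"),
                                 transfer = "V2", alpha = 0.99,
                                 pop_size = 10, max_iter = 100,
                                 max_ffes = NULL, runs = 20, k = 5,
                                 folds = 10, cls_steps = 4,
                                 cls_trigger = NULL, companion_box = 4,
                                 step_scale = NULL, init_density = 0.2,
                                 scale = TRUE, seed = 1, ...) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features contain missing values; impute first ",
                     "(read_dataset() mean-imputes)", call. = FALSE)
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  if (min(table(y)) < folds) {
    stop("every class needs at least 'folds' samples", call. = FALSE)
  }
  O <- ncol(x)
  if (is.null(max_ffes)) max_ffes <- ffe_budget(pop_size, max_iter)
  if (is.null(cls_trigger)) cls_trigger <- floor(max_ffes / 3)
  if (is.null(step_scale)) step_scale <- 4 / O
  if (max_ffes < 2 * pop_size) {
    stop("budget must cover the 2 * pop_size initialization evaluations",
         call. = FALSE)
  }
  feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(O))

  xs <- if (scale) scale_minmax(x) else structure(x,
    scale_lo = rep(0, O), scale_hi = rep(1, O))

  run_out <- lapply(seq_len(runs), function(r) {
    run_binary_swarm(xs, y, algorithm, transfer, alpha, as.integer(pop_size),
                     as.integer(max_ffes), as.integer(cls_steps),
                     as.integer(cls_trigger), companion_box, step_scale,
                     init_density, k, folds,
                     run_seed = substream_seed(seed, "runs", r))
  })

  fitness <- vapply(run_out, `[[`, 0, "fitness")
  masks <- do.call(rbind, lapply(run_out, `[[`, "bits"))
  colnames(masks) <- feature_names
  best_run <- which.min(fitness)
  best_mask <- masks[best_run, ]

  # final accuracy recomputed under the same CV protocol with a fixed
  # reporting partition
  final_er <- knn_error(xs, y, best_mask, k = k, n_folds = folds,
                        fold_seed = substream_seed(seed, "folds"))

  structure(list(
    call = match.call(),
    algorithm = algorithm, transfer = transfer, alpha = alpha,
    pop_size = pop_size, max_ffes = max_ffes, runs_n = runs,
    k = k, folds = folds, seed = seed, step_scale = step_scale,
    n_features = O, feature_names = feature_names,
    selected = stats::setNames(best_mask, feature_names),
    best_fitness = fitness[best_run],
    mean_fitness = mean(fitness),
    sd_fitness = stats::sd(fitness),
    error_rate = final_er,
    accuracy = 1 - final_er,
    selection_ratio = selection_ratio(best_mask),
    runs = data.frame(run = seq_len(runs),
                      best_fitness = fitness,
                      n_selected = rowSums(masks),
                      ffes_used = vapply(run_out, `[[`, 0L, "ffes_used")),
    masks = masks,
    frequency = colMeans(masks),
    trace = run_out[[best_run]]$trace,
    train = list(x = xs, y = y,
                 scale_lo = attr(xs, "scale_lo"),
                 scale_hi = attr(xs, "scale_hi"))
  ), class = "coffo_fs")
}

#' @export
print.coffo_fs <- function(x, ...) {
  cat(sprintf("Wrapper feature selection by binary %s (%s, alpha = %g)\n",
              toupper(x$algorithm), x$transfer, x$alpha))
  cat(sprintf("  %d runs x %d FFEs on %d features\n",
              x$runs_n, x$max_ffes, x$n_features))
  cat(sprintf("  best fitness %.4f (mean %.4f, sd %.4f over runs)\n",
              x$best_fitness, x$mean_fitness, x$sd_fitness))
  cat(sprintf("  selected %d/%d features (ratio %.4f), CV accuracy %.4f\n",
              sum(x$selected), x$n_features, x$selection_ratio, x$accuracy))
  cat("  features:", paste(x$feature_names[x$selected], collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.coffo_fs <- function(object, ...) {
  structure(list(fit = object), class = "summary.coffo_fs")
}

#' @export
print.summary.coffo_fs <- function(x, ...) {
  print(x$fit)
  cat("\nPer-run best fitness:\n")
  print(summary(x$fit$runs$best_fitness))
  cat("\nSelection frequency across runs (most frequent first):\n")
  fr <- sort(x$fit$frequency, decreasing = TRUE)
  print(round(fr[fr > 0], 3))
  invisible(x)
}

#' @export
coef.coffo_fs <- function(object, ...) {
  stats::setNames(as.integer(object$selected), object$feature_names)
}

#' Classify new samples with the selected feature subset
#'
#' Applies the training min-max scaling to `newdata` and classifies each row
#' by the same KNN rule used during selection, restricted to the selected
#' features.
#'
#' @param object A fitted `coffo_fs` object.
#' @param newdata Numeric matrix or data frame with the original feature
#'   columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.coffo_fs <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata must have ", object$n_features, " feature columns",
         call. = FALSE)
  }
  tr <- object$train
  ns <- scale_minmax(newdata, lo = tr$scale_lo, hi = tr$scale_hi)
  m <- object$selected
  knn_predict(tr$x[, m, drop = FALSE], ns[, m, drop = FALSE],
              tr$y, object$k)
}

#' Plot a feature-selection fit
#'
#' `type = "frequency"` draws the per-feature selection frequency across
#' runs; `type = "trace"` the best run's best-so-far fitness trace.
#'
#' @param x A `coffo_fs` object.
#' @param type `"frequency"` or `"trace"`.
#' @param ... Further graphical parameters.
#' @export
plot.coffo_fs <- function(x, type = c("frequency", "trace"), ...) {
  type <- match.arg(type)
  if (type == "frequency") {
    graphics::barplot(x$frequency, las = 2, cex.names = 0.7,
                      ylab = "selection frequency across runs",
                      col = ifelse(x$selected, "steelblue", "grey80"), ...)
  } else {
    plot(x$trace$ffe, x$trace$best, type = "s",
         xlab = "fitness function evaluations", ylab = "best fitness", ...)
  }
  invisible(x)
}
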