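# KNN wrapper fitness machinery: stratified fold construction and the
# cross-validated classification error of a masked feature set.

#' Stratified cross-validation fold assignment
#'
#' Partitions samples into `n_folds` folds whose class proportions match the
#' full data within one sample per class: within each class the (shuffled)
#' members are dealt round-robin to the folds.
#'
#' @param labels Vector of class labels.
#' @param n_folds Number of folds.
#' @param seed Optional seed for the shuffle; `NULL` uses the current RNG
#'   stream.
#' @return Integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = NULL) {
  labels <- as.factor(labels)
  if (min(table(labels)) < n_folds) {
    stop("every class must have at least as many samples as folds",
         call. = FALSE)
  }
  assign_folds <- function() {
    fold <- integer(length(labels))
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes to keep fold sizes balanced
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
    fold
  }
  if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
}

# deterministic KNN prediction: Euclidean distance, majority over the k
# nearest with symmetric fractional handling of distance ties — neighbours
# strictly closer than the k-th distance vote fully, neighbours tied at the
# k-th distance share the remaining seats in proportion to their classes.
# Coarse integer features produce massive distance ties; a rule that picks
# arbitrary tie members (by index or at random) turns tie-breaking into a
# lottery and hands spurious value to unique-valued junk columns (e.g. a
# patient id) purely as tie-breakers. The expected-vote rule is index-free,
# deterministic, and reduces to plain KNN on tie-free data. Vote ties go to
# the first class level.
knn_predict <- function(train, test, cl, k) {
  cl <- as.factor(cl)
  nlev <- nlevels(cl)
  ci <- as.integer(cl)
  d2 <- outer(rowSums(test^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(test)), rowSums(train^2)) -
    2 * tcrossprod(test, train)
  k <- min(k, nrow(train))
  out <- integer(nrow(test))
  for (i in seq_len(nrow(test))) {
    dv <- d2[i, ]
    dk <- sort.int(dv, partial = k)[k]
    tol <- 1e-9 * (1 + abs(dk))
    inner <- dv < dk - tol
    tied <- abs(dv - dk) <= tol
    votes <- tabulate(ci[inner], nlev)
    seats <- k - sum(inner)
    votes <- votes + seats * tabulate(ci[tied], nlev) / sum(tied)
    out[i] <- which.max(votes)
  }
  factor(levels(cl)[out], levels = levels(cl))
}

#' Cross-validated KNN error of a feature mask
#'
#' Stratified `n_folds`-fold cross-validation of a k-nearest-neighbour
#' classifier (majority vote, Euclidean distance, deterministic lowest-index
#' tie-breaking) restricted to the masked features. The fold assignment is
#' either supplied (so that every fitness evaluation within one optimization
#' run reuses the same partition, making the mask-to-error cache exact) or
#' built from `fold_seed`.
#'
#' @param x Numeric feature matrix (samples in rows), already scaled.
#' @param y Class labels.
#' @param mask Logical vector selecting features; must select at least one.
#' @param k Number of neighbours (default 5).
#' @param n_folds Number of folds (default 10).
#' @param fold_seed Seed used to build the fold assignment when `folds` is
#'   not supplied.
#' @param folds Optional precomputed fold assignment from
#'   [stratified_folds()].
#' @return The misclassification rate in `[0, 1]`.
#' @export
knn_error <- function(x, y, mask, k = 5, n_folds = 10, fold_seed = 1,
                      folds = NULL) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask must select at least one feature", call. = FALSE)
  y <- as.factor(y)
  if (is.null(folds)) folds <- stratified_folds(y, n_folds, seed = fold_seed)
  xm <- x[, mask, drop = FALSE]
  wrong <- 0L
  for (f in sort(unique(folds))) {
    test <- folds == f
    pred <- knn_predict(xm[!test, , drop = FALSE],
                        xm[test, , drop = FALSE], y[!test], k)
    wrong <- wrong + sum(pred != y[test])
  }
  wrong / length(y)
}

# per-column min-max scaling to [0, 1]; constant columns map to 0
scale_minmax <- function(x, lo = NULL, hi = NULL) {
  if (is.null(lo)) lo <- apply(x, 2, min)
  if (is.null(hi)) hi <- apply(x, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  out <- sweep(sweep(x, 2, lo, "-"), 2, span, "/")
  attr(out, "scale_lo") <- lo
  attr(out, "scale_hi") <- hi
  out
}
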