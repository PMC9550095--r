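# V-shaped transfer functions and the bit-flip binarization rule that adapts
# the continuous optimizers to feature subset search.

#' V-shaped transfer functions
#'
#' Map a continuous value to a flip probability in `[0, 1)`. V-shaped
#' transfer functions measure displacement magnitude: they are even, vanish
#' at 0 and saturate towards 1 as `|x|` grows, so large moves in the
#' continuous companion space translate into likely bit flips.
#'
#' * `V1`: `|erf(sqrt(pi)/2 * x)|`
#' * `V2`: `|tanh(x)|`
#' * `V3`: `|x / sqrt(1 + x^2)|`
#' * `V4`: `|(2/pi) * atan(pi/2 * x)|`
#'
#' @param name One of `"V1"`, `"V2"`, `"V3"`, `"V4"`.
#' @param x Finite numeric vector.
#' @return Flip probabilities in `[0, 1)`, same length as `x`.
#' @examples
#' transfer_v("V3", 1)  # 1/sqrt(2)
#' @export
transfer_v <- function(name, x) {
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  switch(match.arg(name, c("V1", "V2", "V3", "V4")),
    V1 = abs(2 * stats::pnorm(sqrt(pi) / 2 * x * sqrt(2)) - 1),
    V2 = abs(tanh(x)),
    V3 = abs(x / sqrt(1 + x^2)),
    V4 = abs(2 / pi * atan(pi / 2 * x))
  )
}

#' Stochastic bit-flip binarization
#'
#' For each feature `j`, the bit is complemented with probability
#' `T(values[j])` under the chosen V-shaped transfer function, otherwise
#' retained. If the resulting mask is empty it is repaired by setting one
#' uniformly random bit, so downstream fitness evaluations never see an
#' empty feature subset.
#'
#' @param bits Logical vector, the current feature mask.
#' @param values Numeric vector (same length) fed to the transfer function;
#'   in the search driver this is the continuous displacement of the
#'   companion position.
#' @param tf Transfer function name, see [transfer_v()].
#' @return The new logical mask, never empty.
#' @export
binarize_step <- function(bits, values, tf = "V2") {
  stopifnot(length(bits) == length(values))
  p <- transfer_v(tf, values)
  flip <- stats::runif(length(bits)) < p
  out <- xor(bits, flip)
  repair_mask(out)
}

# empty-mask repair: set one uniformly random bit
repair_mask <- function(bits) {
  if (!any(bits)) bits[sample.int(length(bits), 1L)] <- TRUE
  bits
}

#' Feature selection ratio
#'
#' The fraction `|S| / |O|` of original features retained by a mask.
#'
#' @param mask Logical (or 0/1) vector.
#' @return A number in `(0, 1]`.
#' @examples
#' selection_ratio(c(TRUE, FALSE, TRUE, FALSE, FALSE))  # 0.4
#' @export
selection_ratio <- function(mask) {
  if (!any(as.logical(mask))) stop("mask must select at least one feature",
                                   call. = FALSE)
  sum(as.logical(mask)) / length(mask)
}

#' Wrapper feature-selection fitness
#'
#' The weighted compromise `alpha * ER + (1 - alpha) * |S| / |O|` between
#' the cross-validated classification error `ER` of the masked feature set
#' and the fraction of features retained. With the conventional
#' `alpha = 0.99` the error dominates and the subset-size term breaks ties
#' between masks of equal accuracy.
#'
#' @param er Classification error rate in `[0, 1]`.
#' @param subset_size Number of selected features, `>= 1`.
#' @param total Total number of features.
#' @param alpha Error weight in `[0, 1]`; the size weight is `1 - alpha`.
#' @return The scalar fitness (lower is better).
#' @examples
#' fs_fitness(0.1, 5, 10, alpha = 0.99)  # 0.104
#' @export
fs_fitness <- function(er, subset_size, total, alpha = 0.99) {
  if (subset_size < 1) stop("subset_size must be >= 1 (empty masks are ",
                            "repaired before evaluation)", call. = FALSE)
  if (er < 0 || er > 1) stop("er must lie in [0, 1]", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  alpha * er + (1 - alpha) * subset_size / total
}
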