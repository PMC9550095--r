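# Download-free generators of two-class classification data with a planted
# informative feature subset, used to exercise and validate the wrapper
# feature selection without external datasets.

#' Generate a two-class dataset with planted informative features
#'
#' Labels are Bernoulli(`class_balance`). `n_informative` feature columns
#' carry signal: class means at `-effect_size / 2` and `+effect_size / 2`
#' with unit Gaussian noise, so `effect_size` is the class-mean separation
#' in noise standard deviations. The remaining columns are standard normal,
#' independent of the label. Column order is randomly permuted and the
#' planted indices are reported post-permutation.
#'
#' @param n_samples Number of rows.
#' @param n_features Total number of feature columns `O`.
#' @param n_informative Number of signal-carrying columns `s`, `1 <= s <= O`
#'   (0 is allowed and yields pure noise).
#' @param effect_size Class-mean separation Delta `>= 0` in noise-SD units.
#' @param class_balance Probability of class `1`, default 0.5.
#' @param seed Seed for the generator substream.
#' @return List of class `synth_data`: `features` (matrix with named
#'   columns), `labels` (factor `0`/`1`), `informative` (integer indices of
#'   the planted columns after permutation).
#' @examples
#' d <- generate_classification(100, 20, 3, effect_size = 2, seed = 1)
#' d$informative
#' @export
generate_classification <- function(n_samples = 200, n_features = 50,
                                    n_informative = 5, effect_size = 2,
                                    class_balance = 0.5, seed = 1) {
  if (n_informative > n_features) {
    stop("n_informative cannot exceed n_features", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  with_seed(substream_seed(seed, "synth"), {
    y <- stats::rbinom(n_samples, 1, class_balance)
    shift <- (y - 0.5) * effect_size  # -Delta/2 for class 0, +Delta/2 for 1
    X <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    if (n_informative > 0) {
      X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] + shift
    }
    perm <- sample.int(n_features)
    X <- X[, perm, drop = FALSE]
    informative <- which(perm <= n_informative)
    colnames(X) <- paste0("f", seq_len(n_features))
    structure(list(features = X, labels = factor(y),
                   informative = sort(informative)),
              class = "synth_data")
  })
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("Synthetic two-class dataset: %d samples x %d features, %d informative\n",
              nrow(x$features), ncol(x$features), length(x$informative)))
  if (length(x$informative)) {
    cat("  planted columns:",
        paste(colnames(x$features)[x$informative], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a COVID-like 15-feature patient table
#'
#' A synthetic stand-in for a small tabular COVID-19 patient dataset with a
#' binary death/recovery outcome and 15 numerically encoded features
#' (patient id, location, country, gender, age, two date stamps, two
#' Wuhan-exposure indicators and six clinical symptoms). A configurable
#' subset of features (default gender, age and symptom_2) carries signal
#' through class-conditional distributions; the id column (and by default
#' symptom_6) is independent of the outcome by construction, so a sound
#' wrapper selector should discard it.
#'
#' @param n_samples Number of patients, default 400.
#' @param death_rate Probability of the death outcome, default 0.3.
#' @param seed Generator seed.
#' @return A `synth_data` list: `features` (15 named numeric columns),
#'   `labels` (factor, `recov`/`death`), `informative` (indices of the
#'   signal-carrying columns).
#' @export
generate_covidlike <- function(n_samples = 400, death_rate = 0.3, seed = 1) {
  with_seed(substream_seed(seed, "synth"), {
    n <- n_samples
    death <- stats::rbinom(n, 1, death_rate)
    # class-conditional signal calibrated so the selected-subset CV
    # accuracy lands near the low-90s operating point typical of small
    # clinical outcome tables
    age <- round(ifelse(death == 1, stats::rnorm(n, 66, 10),
                        stats::rnorm(n, 40, 12)))
    age <- pmin(pmax(age, 1), 99)
    gender <- stats::rbinom(n, 1, ifelse(death == 1, 0.70, 0.40))
    sympt2 <- ifelse(death == 1,
                     sample(0:3, n, TRUE, prob = c(.05, .15, .30, .50)),
                     sample(0:3, n, TRUE, prob = c(.50, .30, .15, .05)))
    X <- cbind(
      id = sample.int(n),
      location = sample.int(25, n, TRUE),
      country = sample.int(8, n, TRUE),
      gender = gender,
      age = age,
      sym_on = sample.int(60, n, TRUE),
      hosp_vis = sample.int(60, n, TRUE),
      vis_wuhan = stats::rbinom(n, 1, 0.2),
      from_wuhan = stats::rbinom(n, 1, 0.25),
      symptom_1 = sample(0:3, n, TRUE),
      symptom_2 = sympt2,
      symptom_3 = sample(0:3, n, TRUE),
      symptom_4 = sample(0:2, n, TRUE),
      symptom_5 = sample(0:2, n, TRUE),
      symptom_6 = sample(0:1, n, TRUE)
    )
    structure(list(
      features = X,
      labels = factor(ifelse(death == 1, "death", "recov"),
                      levels = c("recov", "death")),
      informative = which(colnames(X) %in% c("gender", "age", "symptom_2"))
    ), class = "synth_data")
  })
}

#' Jaccard index between two feature masks
#'
#' `|A intersect B| / |A union B|` on the selected-feature sets; the
#' planted-subset recovery score used to validate the wrapper.
#'
#' @param a,b Logical masks or integer index vectors.
#' @param n_features Total number of features (needed when indices are
#'   given).
#' @return A number in `[0, 1]` (1 when both masks are empty).
#' @export
mask_jaccard <- function(a, b, n_features = NULL) {
  to_idx <- function(m) {
    if (is.logical(m)) which(m) else as.integer(m)
  }
  ia <- to_idx(a)
  ib <- to_idx(b)
  u <- length(union(ia, ib))
  if (u == 0) return(1)
  length(intersect(ia, ib)) / u
}
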