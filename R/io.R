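# Dataset and result-table readers/writers for the command-line and script
# workflows. CSV files carry a header row with the class label in the last
# column; ARFF files follow the standard and are read via foreign.

#' Read a classification dataset from CSV or ARFF
#'
#' The last column is taken as the class label; all other columns become
#' the feature matrix. Non-numeric feature columns are label-encoded to
#' integers (0-based, by level order); missing feature values are
#' mean-imputed per column with a warning.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"csv"` or `"arff"`.
#' @return List of class `fs_dataset`: `features` (numeric matrix),
#'   `labels` (factor with at least two levels), `feature_names`.
#' @export
read_dataset <- function(path, format = c("auto", "csv", "arff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  df <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    arff = foreign::read.arff(path)
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("empty or degenerate dataset: need >= 1 row and >= 2 columns",
         call. = FALSE)
  }
  labels <- as.factor(df[[ncol(df)]])
  if (nlevels(labels) < 2) {
    stop("label column has a single class; not a classification dataset",
         call. = FALSE)
  }
  feat <- df[, -ncol(df), drop = FALSE]
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      feat[[j]] <- as.numeric(as.factor(feat[[j]])) - 1
    }
  }
  X <- as.matrix(feat)
  if (anyNA(X)) {
    warning("missing feature values mean-imputed per column")
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  structure(list(features = X, labels = labels,
                 feature_names = colnames(X)),
            class = "fs_dataset")
}

#' @export
print.fs_dataset <- function(x, ...) {
  cat(sprintf("Classification dataset: %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), nlevels(x$labels)))
  invisible(x)
}

.results_schema <- "coffo-results-v1"

#' Write a results table to CSV
#'
#' Writes a data frame with a schema-version comment line so the companion
#' [read_results()] can round-trip it.
#'
#' @param results A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .results_schema), con)
  utils::write.csv(results, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a synthetic dataset to CSV with a planted-index sidecar
#'
#' The CSV has a header row and the label in the last column (the layout
#' [read_dataset()] expects); the sidecar `<path>.meta.json`-style text file
#' lists the planted informative column indices, one per line.
#'
#' @param data A `synth_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synth_csv <- function(data, path) {
  df <- as.data.frame(data$features)
  df$label <- data$labels
  utils::write.csv(df, path, row.names = FALSE)
  writeLines(as.character(data$informative),
             paste0(path, ".planted.txt"))
  invisible(path)
}
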