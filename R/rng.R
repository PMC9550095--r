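# Named random substreams. Every user-facing entry point takes one root seed;
# components (initialization, search, fold construction, data synthesis, run
# replicates) derive their own sub-seeds from it so each can be reproduced in
# isolation. Kept below 2^31 - 1 to stay a valid R integer seed.

.substream_offsets <- c(init = 1L, search = 2L, folds = 3L, synth = 4L,
                        runs = 5L, cls = 6L)

substream_seed <- function(seed, name, index = 0L) {
  off <- .substream_offsets[[name]]
  if (is.null(off)) stop("unknown substream '", name, "'", call. = FALSE)
  v <- (as.numeric(seed) %% 2147483647) * 48271 +
    off * 69621 + as.numeric(index) * 16807
  as.integer(v %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
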