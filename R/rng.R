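# Deterministic seed derivation. All randomness in a run descends from one
# master seed through named substreams ("init", "schedule", "mutation",
# "trial", ...), so each component is independently reproducible.

#' Derive a substream seed from a master seed
#'
#' Hashes the master seed together with a sequence of labels/indices into a
#' positive integer below 2^31 - 1, using repeated multiply-add modulo the
#' Mersenne prime 2147483647. Deterministic and portable.
#'
#' @param master Non-negative integer master seed.
#' @param ... Labels (strings) and indices (numbers) naming the substream.
#' @return Integer seed in \code{[1, 2147483646]}.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- (as.numeric(master) %% m) + 1
  for (part in list(...)) {
    ks <- if (is.character(part)) as.numeric(utf8ToInt(part)) else as.numeric(part)
    for (k in ks) {
      h <- (h * 48271 + k + 1) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}

# evaluate expr under a temporary R RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
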