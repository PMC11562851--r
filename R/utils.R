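## Internal helpers: deterministic substreams and logging.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stable 31-ary string hash, folded into [0, 2^31 - 22)
#'
#' Used to derive independent, order-invariant RNG substreams per
#' (seed gene, pathway) pair. Pure double arithmetic; intermediate
#' products stay below 2^53 so the result is exact.
#' @noRd
.pd_hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483629
  h
}

## Deterministic seed for a named substream; always in [1, 2^31).
.pd_stream_seed <- function(rng_seed, ...) {
  .pd_hash_string(paste(rng_seed, ..., sep = "\r")) + 1
}

## Evaluate `code` under set.seed(seed) without disturbing the caller's
## RNG state (restores .Random.seed, or removes it if it did not exist).
.pd_with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.pd_msg <- function(fmt, ..., verbose = getOption("pleiodrug.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
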