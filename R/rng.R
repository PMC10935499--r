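# Deterministic seed hierarchy: one master seed drives named sub-streams so
# any component (cohort draw, shard draw, epoch shuffle, learner init) can be
# reproduced in isolation.

#' Derive a child seed from a master seed and a path of tags
#'
#' Hashes the master seed together with an arbitrary path of tags (strings or
#' integers) into a deterministic 31-bit seed. Used throughout the package so
#' that cohort generation, sharding, learner initialization and epoch
#' shuffling each consume an independent, reproducible random stream.
#'
#' @param seed Integer master seed.
#' @param ... Path components (coerced to character) naming the sub-stream.
#' @return A positive integer strictly below 2^31.
#' @export
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "shard", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  path <- paste(c(format(seed, scientific = FALSE), vapply(list(...), as.character, "")),
                collapse = "/")
  bytes <- utf8ToInt(path)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1L)
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
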