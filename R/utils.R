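# Internal helpers shared across modules.

# Deterministic 31-bit polynomial string hash (base 131, modulus the
# Mersenne prime 2^31 - 1; products stay below 2^39, exact in doubles).
# Used to derive per-node / per-replicate RNG substreams from a root seed,
# so that adding a variable to a schema never perturbs the draws of others.
fnv1a31 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

#' Derive a deterministic RNG substream seed
#'
#' Combines a root seed with a character key (a node name, a bootstrap
#' replicate label, ...) into a reproducible 31-bit seed. The map is a fixed
#' hash, so substreams for different keys are effectively independent and
#' stable across sessions.
#'
#' @param seed Integer root seed.
#' @param key Character scalar naming the substream.
#' @return A single integer suitable for [set.seed()].
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  as.integer((fnv1a31(paste0(key, ":", format(seed))) +
                as.double(seed) * 48271) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# error with a consistent class so tests can be specific
bn_abort <- function(msg, class = "behavnet_error") {
  rlang::abort(msg, class = class)
}
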