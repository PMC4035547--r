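# Deterministic seed substreams.
#
# One master seed drives a whole study; each operation (and each
# replicate inside the power engine) seeds R's RNG with a value derived
# from (master seed, operation tag, index). Derived seeds stay inside
# the 32-bit integer range set.seed() accepts.

SEED_MOD <- 2147483647  # 2^31 - 1

derive_seed <- function(seed, tag, index = 0L) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed %% SEED_MOD)
  for (ch in utf8ToInt(tag)) h <- (h * 69069 + ch) %% SEED_MOD
  h <- (h * 69069 + as.double(index)) %% SEED_MOD
  as.integer(h)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(seed)
}
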