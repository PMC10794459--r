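# Run `expr` under a temporary RNG state when a seed is given, otherwise use
# the session RNG as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one master seed, so independent stages
# (population draw, schedule, responses) do not share RNG streams.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  withr::with_seed(as.integer(seed),
                   as.list(sample.int(.Machine$integer.max, n)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
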