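# Seed management. One user-facing seed per dataset/run is split into named
# substreams so that, e.g., switching the noise family leaves the design
# matrix draw untouched (paired comparisons across noise families).

#' Derive a deterministic sub-seed from a base seed and a stream name
#'
#' @param seed integer base seed.
#' @param stream character label of the substream (e.g. `"X"`, `"E"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes) * 2654435.0) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
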