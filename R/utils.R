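# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers a user's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-unit seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + as.double(index)) %%
               2147483563) + 1L
}
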