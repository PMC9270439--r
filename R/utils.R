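# Internal helpers shared across modules.

# Deterministic, platform-independent seed for a (master seed, label) pair.
# Keeps the result strictly below 2^31 so set.seed() accepts it everywhere.
derive_seed <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  # take 7 hex digits -> < 2^28
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

# Evaluate `expr` with a local RNG state seeded at `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable content hash used in output headers and the run manifest.
config_hash <- function(x) rlang::hash(x)

assert_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
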