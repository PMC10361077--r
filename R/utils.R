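# Deterministic seeding: a master seed spawns named substreams so that each
# stage (per-population subsampling, null model, Monte Carlo, permutations)
# is reproducible independently of the order in which stages run.

MOD31 <- 2147483647  # 2^31 - 1

hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% MOD31
  h
}

substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((((master %% MOD31) * 48271) %% MOD31 + hash_string(name)) %% MOD31)
}

## evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
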