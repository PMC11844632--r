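# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of mixed numeric/character tokens, used to derive
# independent sub-seeds (map, plan, restart) from one base seed. Kept below
# 2^31 - 1 so the result is always a valid R integer seed.
.hash_seed <- function(...) {
  tokens <- list(...)
  m <- 2147483647
  h <- 17
  for (tok in tokens) {
    if (is.character(tok)) {
      codes <- unlist(lapply(tok, utf8ToInt), use.names = FALSE)
    } else {
      codes <- as.numeric(tok)
      # fold doubles onto integers reproducibly
      codes <- floor(abs(codes) * 1000 + 0.5) %% m
    }
    for (e in codes) h <- (h * 31 + e) %% m
  }
  as.integer(h)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
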