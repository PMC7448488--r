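# Internal helpers: seeding, hashing, logging.

# Polynomial rolling hash of a character string, kept below 2^31 so it is
# a valid R integer seed. 2147483629 is prime; 31 is the usual multiplier.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

# Deterministic per-stage seed derived from a master seed and a stage name.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  as.integer((as.double(master) + fnv1a_hash(stage)) %% 2147483647)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Short content hash of an R object (used to stamp outputs with their config).
object_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 17
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

log_msg <- function(...) {
  message(sprintf(...))
}
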