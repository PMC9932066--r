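# Internal helpers shared across modules.

POLLINATOR_GROUPS <- c("wild_bee", "hoverfly", "butterfly", "honey_bee")

# Evaluate expr with a temporary RNG state; restores the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Commercial rounding (half away from zero), used for printed percentage
# shares so that 54.315 -> 54 and 22.5 -> 23 regardless of IEEE round-to-even.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 32-bit FNV-1a over serialized R objects; a light content fingerprint for
# run manifests (no cryptographic intent).
fnv1a32 <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2))
  # skip the serialization header (version-dependent bytes)
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep arithmetic in doubles
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # h * 16777619 mod 2^32 without overflow: split into 16-bit halves
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * 16777619) %% 4294967296 + ((hi * 16777619) %% 65536) * 65536) %%
      4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# x %||% y
`%||%` <- function(a, b) if (is.null(a)) b else a

# entropy of a non-negative weight vector after normalisation, in nats;
# zero cells contribute 0
shannonEntropy <- function(w) {
  w <- w[w > 0]
  p <- w / sum(w)
  -sum(p * log(p))
}

assertCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x != round(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  }
  as.integer(x)
}
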