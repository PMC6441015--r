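# Internal helpers: seeded evaluation and base/k-mer integer coding.

.BASES <- c("A", "C", "G", "T")

.CODE <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 0L
  x[utf8ToInt("C")] <- 1L
  x[utf8ToInt("G")] <- 2L
  x[utf8ToInt("T")] <- 3L
  x
})

.COMP <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- utf8ToInt("T")
  x[utf8ToInt("T")] <- utf8ToInt("A")
  x[utf8ToInt("C")] <- utf8ToInt("G")
  x[utf8ToInt("G")] <- utf8ToInt("C")
  x
})

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded package functions do not perturb user sessions.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

base_codes <- function(s) {
  v <- utf8ToInt(s)
  out <- .CODE[v]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("invalid base '%s' at position %d (alphabet is A/C/G/T)",
                 intToUtf8(v[bad]), bad))
  }
  out
}

codes_to_string <- function(codes) {
  if (length(codes) == 0L) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
}

revcomp <- function(s) {
  v <- utf8ToInt(s)
  out <- .COMP[rev(v)]
  if (anyNA(out)) stop("invalid base in sequence passed to revcomp()")
  intToUtf8(out)
}

# Integer codes of every k-mer (Horner scheme, first base most significant).
# Returns length(codes) - k + 1 values in [0, 4^k).
kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  acc <- integer(n - k + 1L)
  for (i in seq_len(k)) acc <- acc * 4L + codes[i:(n - k + i)]
  acc
}

# Deterministic sub-seed derivation that stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + 7919L * as.numeric(i)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
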