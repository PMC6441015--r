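# Independent exhaustive oracles, kept free of the package's alignment code.

# Full-matrix semi-global DP (query global, reference ends free; match +1,
# mismatch/gap -1) maximizing (score, matches) lexicographically. Returns the
# best (score, matches) over the final row.
oracle_semiglobal <- function(q_codes, r_codes) {
  n <- length(q_codes)
  m <- length(r_codes)
  S <- rep(0, m + 1)        # row 0: free reference start
  M <- rep(0, m + 1)
  for (i in seq_len(n)) {
    Sn <- rep(-Inf, m + 1)
    Mn <- rep(0, m + 1)
    Sn[1] <- S[1] - 1       # j = 0: query prefix against gaps
    Mn[1] <- M[1]
    for (j in seq_len(m)) {
      mt <- q_codes[i] == r_codes[j]
      bs <- S[j] + if (mt) 1 else -1
      bm <- M[j] + mt
      if (S[j + 1] - 1 > bs || (S[j + 1] - 1 == bs && M[j + 1] > bm)) {
        bs <- S[j + 1] - 1; bm <- M[j + 1]
      }
      if (Sn[j] - 1 > bs || (Sn[j] - 1 == bs && Mn[j] > bm)) {
        bs <- Sn[j] - 1; bm <- Mn[j]
      }
      Sn[j + 1] <- bs
      Mn[j + 1] <- bm
    }
    S <- Sn
    M <- Mn
  }
  best <- which(S == max(S))
  list(score = max(S), matches = max(M[best]))
}

# Best identity over both strands. With unit scores the alignment-column
# count of an optimal-(score, matches) alignment is 2*matches - score, so
# identity follows from the DP values alone.
oracle_identity <- function(query, ref_bases) {
  qc <- poredose:::base_codes(query)
  rc <- poredose:::base_codes(ref_bases)
  fwd <- oracle_semiglobal(qc, rc)
  rev <- oracle_semiglobal(rev(3L - qc), rc)
  pick <- fwd
  if (rev$score > pick$score ||
      (rev$score == pick$score && rev$matches > pick$matches)) {
    pick <- rev
  }
  pick$matches / (2 * pick$matches - pick$score)
}

# Infix edit distance (pattern fully consumed, free text ends).
oracle_edit_infix <- function(pattern, text) {
  pc <- poredose:::base_codes(pattern)
  tc <- poredose:::base_codes(text)
  np <- length(pc)
  nt <- length(tc)
  D <- matrix(0L, np + 1, nt + 1)
  D[, 1] <- 0:np
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      D[i + 1, j + 1] <- min(D[i, j] + (pc[i] != tc[j]),
                             D[i, j + 1] + 1L, D[i + 1, j] + 1L)
    }
  }
  min(D[np + 1, ])
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
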