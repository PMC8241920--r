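# Independent oracles, kept deliberately simple and separate from the
# implementation paths they check.

# Affine-gap local alignment by direct dynamic programming over three
# matrices. Convention: a gap of length L costs open + L * ext.
sw_oracle <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exhaustive CB maximization over all span pairs, with the same
# tie-breaking rule (smaller total length, then leftmost) implemented
# independently of trim_boundaries.
cb_naive <- function(ai, bi, s, pen, i1, i2, j1, j2) {
  both <- ai >= i1 & ai <= i2 & bi >= j1 & bi <= j2
  matched_a <- 0
  if (any(both))
    matched_a <- sum(tapply(s[both], ai[both], max))
  n_ma <- length(unique(ai[both]))
  n_mb <- length(unique(bi[both]))
  matched_a + pen * ((i2 - i1 + 1 - n_ma) + (j2 - j1 + 1 - n_mb))
}

trim_oracle <- function(nA, nB, ai, bi, s, pen) {
  best <- NULL
  for (i1 in 1:nA) for (i2 in i1:nA) for (j1 in 1:nB) for (j2 in j1:nB) {
    cb <- cb_naive(ai, bi, s, pen, i1, i2, j1, j2)
    tlen <- (i2 - i1 + 1) + (j2 - j1 + 1)
    if (is.null(best) || cb > best$cb + 1e-9 ||
        (abs(cb - best$cb) <= 1e-9 &&
         (tlen < best$tlen ||
          (tlen == best$tlen &&
           (i1 < best$i1 || (i1 == best$i1 &&
            (j1 < best$j1 || (j1 == best$j1 &&
             (i2 < best$i2 || (i2 == best$i2 && j2 < best$j2))))))))))
      best <- list(cb = cb, tlen = tlen, i1 = i1, i2 = i2, j1 = j1, j2 = j2)
  }
  best
}

# Exhaustive enumeration of contiguous blocks linked across two gene
# orders, for checking detect_seed on toys: returns the best (longest,
# then highest-scoring, then leftmost) valid block as (a1, a2).
seed_oracle <- function(nA, nB, ai, bi, s, min_len) {
  best <- NULL
  for (a1 in 1:nA) for (a2 in a1:nA) {
    run <- a1:a2
    if (a2 - a1 + 1 < min_len) next
    if (!all(run %in% ai)) next
    bpos <- bi[ai %in% run]
    rng <- min(bpos):max(bpos)
    if (!all(vapply(rng, function(b) any(ai[bi == b] %in% run),
                    logical(1)))) next
    score <- sum(s[ai %in% run & bi %in% rng])
    len <- a2 - a1 + 1
    if (is.null(best) || len > best$len ||
        (len == best$len && score > best$score + 1e-12))
      best <- list(a1 = a1, a2 = a2, len = len, score = score)
  }
  best
}
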