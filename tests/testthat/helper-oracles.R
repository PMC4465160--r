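# Independent brute-force oracles used to pin down the fast implementations.

# O(n*m) bidirectional local distance in plain R.
oracle_bld <- function(ref, tgt) {
  nr <- nrow(ref); nt <- nrow(tgt)
  d <- function(a, b) sqrt(sum((a - b)^2))
  fwd <- sapply(seq_len(nr), function(a)
    min(sapply(seq_len(nt), function(b) d(ref[a, ], tgt[b, ]))))
  out <- fwd
  for (b in seq_len(nt)) {
    dists <- sapply(seq_len(nr), function(a) d(tgt[b, ], ref[a, ]))
    a <- which.min(dists)  # lowest index on ties
    out[a] <- max(out[a], dists[a])
  }
  out
}

# Brute-force physical-distance margin expansion.
oracle_expand <- function(mask, spacing, margin) {
  d <- dim(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dd <- (idx[, 1] - i)^2 * spacing[1]^2 + (idx[, 2] - j)^2 * spacing[2]^2 +
      (idx[, 3] - k)^2 * spacing[3]^2
    if (min(dd) <= margin^2) out[i, j, k] <- 1
  }
  out
}

# Loop-based masked NCC at the identity transform on identical grids.
oracle_ncc_identity <- function(fixed, moving, fmask) {
  f <- fixed[fmask == 1]; m <- moving[fmask == 1]
  sum((f - mean(f)) * (m - mean(m))) /
    sqrt(sum((f - mean(f))^2) * sum((m - mean(m))^2))
}

# Brute-force 6-connected surface voxel count.
oracle_surface_count <- function(mask) {
  d <- dim(mask); n <- 0
  at <- function(i, j, k) {
    if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) 0 else mask[i, j, k]
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] == 0) next
    nb <- c(at(i + 1, j, k), at(i - 1, j, k), at(i, j + 1, k),
            at(i, j - 1, k), at(i, j, k + 1), at(i, j, k - 1))
    if (any(nb == 0)) n <- n + 1
  }
  n
}
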