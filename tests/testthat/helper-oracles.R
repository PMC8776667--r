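# Independent brute-force oracles, deliberately written as plain scalar
# loops so they share no code path with the package implementations.

# GLCM: enumerate every pixel pair at the offset, count both directions.
oracle_glcm <- function(q, offset, levels) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        a <- q[r, c] + 1; b <- q[r2, c2] + 1
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

# LBP codes: per-pixel scalar recomputation with explicit bilinear sampling.
oracle_lbp_codes <- function(patch, P, R) {
  nr <- nrow(patch); nc <- ncol(patch)
  m <- ceiling(R)
  sample_at <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    v <- (1 - fr) * (1 - fc) * patch[r0, c0]
    if (fc > 0) v <- v + (1 - fr) * fc * patch[r0, c0 + 1]
    if (fr > 0) v <- v + fr * (1 - fc) * patch[r0 + 1, c0]
    if (fr > 0 && fc > 0) v <- v + fr * fc * patch[r0 + 1, c0 + 1]
    v
  }
  out <- matrix(NA_real_, nr - 2 * m, nc - 2 * m)
  for (r in (m + 1):(nr - m)) {
    for (c in (m + 1):(nc - m)) {
      code <- 0
      for (p in 0:(P - 1)) {
        a <- 2 * pi * p / P
        dr <- R * sin(a); dc <- R * cos(a)
        if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
        if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
        if (sample_at(r + dr, c + dc) >= patch[r, c]) code <- code + 2^p
      }
      out[r - m, c - m] <- code
    }
  }
  out
}

# AUC: exhaustive positive-negative pair counting, ties worth one half.
oracle_auc <- function(y, scores, positive) {
  pos <- which(y == positive); neg <- which(y != positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Two separable Gaussian blobs in 2-D.
make_blobs <- function(n, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("SCN", "MCN"), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2)
  X[y == "MCN", 1] <- X[y == "MCN", 1] + sep
  list(X = X, y = y)
}

# Meta-feature scenario: one informative column, two noise columns.
make_stacking_data <- function(n, seed = 1) {
  set.seed(seed)
  y <- rep(c("SCN", "MCN"), length.out = n)
  X <- cbind(ifelse(y == "MCN", 1, 0) + rnorm(n, 0, 0.05),
             rnorm(n), rnorm(n))
  list(X = X, y = y)
}
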