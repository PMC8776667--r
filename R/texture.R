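# Handcrafted texture descriptors: GLCM (Haralick subset), LBP, HOG, Gabor
# and Haar-wavelet statistics. Each maps a grayscale patch (the windowed
# channel, values in [0,1]) to a fixed-length numeric vector, so feature
# matrices over a dataset are rectangular for any configuration.

feature_vector <- function(values, name) {
  if (any(!is.finite(values))) {
    cyst_error(sprintf("non-finite values in %s descriptor", name), "cystct_feature_error")
  }
  v <- as.numeric(values)
  names(v) <- names(values)
  structure(v, descriptor = name)
}

# Uniform quantisation of a [0,1] patch into integer levels 0..levels-1.
# Integer-valued patches already below `levels` are passed through.
quantize_levels <- function(patch, levels) {
  if (all(patch == floor(patch)) && max(patch) < levels && min(patch) >= 0) {
    return(matrix(as.integer(patch), nrow(patch), ncol(patch)))
  }
  q <- pmin(floor(pmin(pmax(patch, 0), 1) * levels), levels - 1L)
  matrix(as.integer(q), nrow(patch), ncol(patch))
}

# Symmetric, normalised gray-level co-occurrence matrix for one offset.
glcm_matrix <- function(q, offset, levels) {
  dr <- offset[1]; dc <- offset[2]
  nr <- nrow(q); nc <- ncol(q)
  if (abs(dr) >= nr || abs(dc) >= nc) {
    cyst_error("offset larger than patch", "cystct_offset_error")
  }
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(0, levels, levels)
  idx <- cbind(as.vector(a) + 1L, as.vector(b) + 1L)
  tab <- table(factor(idx[, 1], levels = 1:levels),
               factor(idx[, 2], levels = 1:levels))
  counts <- matrix(as.numeric(tab), levels, levels)
  counts <- counts + t(counts)       # symmetric: count both directions
  counts / sum(counts)
}

glcm_stat_names <- c("contrast", "correlation", "energy", "homogeneity", "entropy")

glcm_stats <- function(P, stats = glcm_stat_names) {
  levels <- nrow(P)
  i <- matrix(0:(levels - 1), levels, levels)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  out <- c(
    contrast = sum((i - j)^2 * P),
    correlation = if (sd_i > 0 && sd_j > 0)
      sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else 1,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2)),
    entropy = -sum(ifelse(P > 0, P * log2(P), 0))
  )
  out[stats]
}

#' GLCM (Haralick) texture features
#'
#' For each pixel offset, builds the symmetric normalised gray-level
#' co-occurrence matrix of the quantised patch and summarises it with
#' contrast, correlation, energy (angular second moment), homogeneity and
#' entropy; the per-offset statistics are concatenated.
#'
#' @param patch grayscale matrix in `[0, 1]` (or already integer-quantised).
#' @param levels number of gray levels (>= 2).
#' @param offsets list of `c(dr, dc)` integer offsets.
#' @param stats subset of
#'   `c("contrast", "correlation", "energy", "homogeneity", "entropy")`.
#' @return Numeric feature vector of length `length(offsets) * length(stats)`.
#' @export
glcm_features <- function(patch, levels = 32L,
                          offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                          stats = glcm_stat_names) {
  check_matrix(patch, "patch")
  if (levels < 2) cyst_error("levels must be >= 2", "cystct_param_error")
  stats <- match.arg(stats, glcm_stat_names, several.ok = TRUE)
  q <- quantize_levels(patch, levels)
  vals <- unlist(lapply(offsets, function(off) {
    glcm_stats(glcm_matrix(q, off, levels), stats)
  }))
  names(vals) <- as.vector(t(outer(
    vapply(offsets, function(o) sprintf("o%d_%d", o[1], o[2]), ""),
    stats, paste, sep = ".")))
  feature_vector(vals, "glcm")
}

# Circular neighbour sampling positions for LBP: angle 2*pi*p/P, offsets
# (dr, dc) = (R sin a, R cos a); bilinear interpolation off the grid.
lbp_codes <- function(patch, P, R) {
  nr <- nrow(patch); nc <- ncol(patch)
  m <- ceiling(R)
  if (nr <= 2 * m + 1 || nc <= 2 * m + 1) {
    cyst_error("patch too small for the requested LBP radius", "cystct_size_error")
  }
  rows <- (m + 1):(nr - m); cols <- (m + 1):(nc - m)
  centre <- patch[rows, cols, drop = FALSE]
  codes <- matrix(0, length(rows), length(cols))
  for (p in 0:(P - 1)) {
    a <- 2 * pi * p / P
    dr <- R * sin(a); dc <- R * cos(a)
    # snap near-integer offsets to the grid to avoid interpolation noise
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    gp <- function(ddr, ddc) patch[rows + ddr, cols + ddc, drop = FALSE]
    # zero-weight corners are skipped: on-grid offsets must not index
    # outside the margin
    nb <- (1 - fr) * (1 - fc) * gp(r0, c0)
    if (fc > 0) nb <- nb + (1 - fr) * fc * gp(r0, c0 + 1)
    if (fr > 0) nb <- nb + fr * (1 - fc) * gp(r0 + 1, c0)
    if (fr > 0 && fc > 0) nb <- nb + fr * fc * gp(r0 + 1, c0 + 1)
    codes <- codes + 2^p * (nb >= centre)
  }
  codes
}

#' Local binary pattern histogram
#'
#' Per-pixel LBP code `sum_p 2^p [neighbor_p >= center]` over `P` circularly
#' interpolated neighbours at radius `R`, histogrammed and normalised to sum
#' to 1. Border pixels without a full neighbourhood are excluded.
#'
#' @param patch grayscale matrix.
#' @param P number of neighbours (>= 4).
#' @param R circle radius in pixels (>= 1).
#' @param bins histogram bins; codes 0..2^P-1 are pooled uniformly when
#'   `bins < 2^P`.
#' @return Normalised histogram of length `bins`.
#' @export
lbp_features <- function(patch, P = 8L, R = 1, bins = 256L) {
  check_matrix(patch, "patch")
  if (P < 4) cyst_error("P must be >= 4", "cystct_param_error")
  if (R < 1) cyst_error("R must be >= 1", "cystct_param_error")
  codes <- lbp_codes(patch, P, R)
  ncodes <- 2^P
  if (bins > ncodes) cyst_error("bins must be <= 2^P", "cystct_param_error")
  binned <- floor(codes / (ncodes / bins))
  h <- tabulate(binned + 1, nbins = bins)
  feature_vector(h / sum(h), "lbp")
}

#' Histogram-of-oriented-gradients descriptor
#'
#' The patch is resized to `resize_to` square (bilinear), gradients taken
#' with central differences, unsigned orientations binned per cell, and
#' overlapping 2x2-cell blocks L2-normalised and concatenated. Descriptor
#' length is constant for a configuration:
#' `(cells - block + 1)^2 * block^2 * bins`.
#'
#' @param patch grayscale matrix.
#' @param cell_size cell side in pixels.
#' @param block_size block side in cells.
#' @param bins unsigned orientation bins over `[0, 180)` degrees.
#' @param resize_to working size in pixels (square).
#' @return Numeric feature vector.
#' @export
hog_features <- function(patch, cell_size = 8L, block_size = 2L, bins = 9L,
                         resize_to = 64L) {
  check_matrix(patch, "patch")
  if (cell_size > resize_to) {
    cyst_error("cell larger than the working patch", "cystct_param_error")
  }
  x <- bilinear_resize(patch, resize_to, resize_to)
  n <- resize_to
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  gx[, 2:(n - 1)] <- x[, 3:n] - x[, 1:(n - 2)]
  gy[2:(n - 1), ] <- x[3:n, ] - x[1:(n - 2), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  ang[ang >= 180] <- 0
  bin <- pmin(floor(ang / (180 / bins)), bins - 1)
  ncell <- n %/% cell_size
  cellh <- array(0, c(ncell, ncell, bins))
  cr <- (row(x) - 1) %/% cell_size + 1
  cc <- (col(x) - 1) %/% cell_size + 1
  keep <- cr <= ncell & cc <= ncell
  for (b in 0:(bins - 1)) {
    sel <- keep & (bin == b) & (mag > 0)
    if (!any(sel)) next
    agg <- tapply(mag[sel], list(factor(cr[sel], 1:ncell), factor(cc[sel], 1:ncell)), sum)
    agg[is.na(agg)] <- 0
    cellh[, , b + 1] <- agg
  }
  nb <- ncell - block_size + 1
  if (nb < 1) cyst_error("block larger than the cell grid", "cystct_param_error")
  out <- numeric(0)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      v <- as.vector(cellh[i:(i + block_size - 1), j:(j + block_size - 1), ])
      nv <- sqrt(sum(v^2))
      out <- c(out, if (nv > 0) v / nv else v)
    }
  }
  feature_vector(out, "hog")
}

gabor_kernel <- function(frequency, theta, sigma = 0.56 / frequency, truncate = 3) {
  r <- max(1L, ceiling(truncate * sigma))
  g <- seq(-r, r)
  X <- outer(g, g, function(rr, cc) cc * cos(theta) + rr * sin(theta))
  Y <- outer(g, g, function(rr, cc) -cc * sin(theta) + rr * cos(theta))
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  list(re = env * cos(2 * pi * frequency * X),
       im = env * sin(2 * pi * frequency * X))
}

#' Gabor filter-bank features
#'
#' Convolves the patch with a bank of complex Gabor filters and reports the
#' mean and standard deviation of the response magnitude per filter, giving
#' a descriptor of length `2 * length(frequencies) * length(orientations)`.
#'
#' @param patch grayscale matrix.
#' @param frequencies spatial frequencies in cycles/pixel.
#' @param orientations filter orientations in radians.
#' @return Numeric feature vector.
#' @export
gabor_features <- function(patch,
                           frequencies = c(0.1, 0.2, 0.3, 0.4),
                           orientations = c(0, pi / 4, pi / 2, 3 * pi / 4)) {
  check_matrix(patch, "patch")
  if (length(frequencies) < 1 || length(orientations) < 1) {
    cyst_error("empty Gabor filter bank", "cystct_param_error")
  }
  out <- numeric(0)
  for (f in frequencies) {
    for (th in orientations) {
      k <- gabor_kernel(f, th)
      # pad the patch if the kernel outsizes it so small ROIs still work
      x <- patch
      if (nrow(x) < nrow(k$re) || ncol(x) < ncol(k$re)) {
        x <- bilinear_resize(x, max(nrow(x), nrow(k$re)), max(ncol(x), ncol(k$re)))
      }
      re <- conv2same(x, k$re); im <- conv2same(x, k$im)
      m <- sqrt(re^2 + im^2)
      out <- c(out, mean(m), stats::sd(as.vector(m)))
    }
  }
  feature_vector(out, "gabor")
}

# One level of the orthonormal 2-D Haar transform (even-sized input).
haar_step <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  s <- 1 / sqrt(2)
  lo_c <- s * (x[, seq(1, nc, 2), drop = FALSE] + x[, seq(2, nc, 2), drop = FALSE])
  hi_c <- s * (x[, seq(1, nc, 2), drop = FALSE] - x[, seq(2, nc, 2), drop = FALSE])
  ll <- s * (lo_c[seq(1, nr, 2), , drop = FALSE] + lo_c[seq(2, nr, 2), , drop = FALSE])
  lh <- s * (hi_c[seq(1, nr, 2), , drop = FALSE] + hi_c[seq(2, nr, 2), , drop = FALSE])
  hl <- s * (lo_c[seq(1, nr, 2), , drop = FALSE] - lo_c[seq(2, nr, 2), , drop = FALSE])
  hh <- s * (hi_c[seq(1, nr, 2), , drop = FALSE] - hi_c[seq(2, nr, 2), , drop = FALSE])
  list(ll = ll, lh = lh, hl = hl, hh = hh)
}

subband_stats <- function(coef) {
  e <- mean(coef^2)
  tot <- sum(coef^2)
  ent <- if (tot > 0) {
    p <- as.vector(coef^2) / tot
    -sum(ifelse(p > 0, p * log2(p), 0))
  } else 0
  c(energy = e, entropy = ent)
}

#' Haar-wavelet subband features
#'
#' Multi-level orthonormal 2-D Haar decomposition; each detail subband (and
#' the final approximation) contributes its energy (mean squared
#' coefficient) and the Shannon entropy of its normalised squared
#' coefficients. Odd-sized inputs are symmetrically padded by one row or
#' column per level as needed.
#'
#' @param patch grayscale matrix with side `>= 2^levels`.
#' @param wavelet wavelet family; only `"haar"` is implemented.
#' @param levels decomposition depth (>= 1).
#' @return Numeric feature vector of length `2 * (3 * levels + 1)`.
#' @export
wavelet_features <- function(patch, wavelet = "haar", levels = 2L) {
  check_matrix(patch, "patch")
  if (!identical(wavelet, "haar")) {
    cyst_error(sprintf("unsupported wavelet: %s", wavelet), "cystct_param_error")
  }
  if (levels < 1) cyst_error("levels must be >= 1", "cystct_param_error")
  if (min(dim(patch)) < 2^levels) {
    cyst_error("patch too small for the requested decomposition depth",
               "cystct_size_error")
  }
  out <- numeric(0); nms <- character(0)
  cur <- patch
  for (l in seq_len(levels)) {
    if (nrow(cur) %% 2 == 1) cur <- rbind(cur, cur[nrow(cur), ])
    if (ncol(cur) %% 2 == 1) cur <- cbind(cur, cur[, ncol(cur)])
    sb <- haar_step(cur)
    for (band in c("lh", "hl", "hh")) {
      st <- subband_stats(sb[[band]])
      out <- c(out, st)
      nms <- c(nms, paste0("L", l, band, "_", names(st)))
    }
    cur <- sb$ll
  }
  st <- subband_stats(cur)
  out <- c(out, st)
  nms <- c(nms, paste0("L", levels, "ll_", names(st)))
  names(out) <- nms
  feature_vector(out, "wavelet")
}

texture_extractors <- c("glcm", "lbp", "hog", "gabor", "wavelet")

#' Dispatch a named texture extractor
#'
#' Convenience front-end used by the pipeline: applies one of the
#' handcrafted extractors to the windowed channel of a patch.
#'
#' @param patch grayscale matrix in `[0, 1]`.
#' @param method one of `"glcm"`, `"lbp"`, `"hog"`, `"gabor"`, `"wavelet"`.
#' @param ... passed to the extractor.
#' @return Numeric feature vector.
#' @export
texture_features <- function(patch, method = texture_extractors, ...) {
  method <- match.arg(method)
  switch(method,
    glcm = glcm_features(patch, ...),
    lbp = lbp_features(patch, ...),
    hog = hog_features(patch, ...),
    gabor = gabor_features(patch, ...),
    wavelet = wavelet_features(patch, ...)
  )
}
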