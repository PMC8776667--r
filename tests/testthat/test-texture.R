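test_that("GLCM worked example: 2x2 patch, offset (0,1), 2 levels", {
  patch <- matrix(c(0, 1, 0, 1), 2)   # rows (0,0) and (1,1)
  fv <- glcm_features(patch, levels = 2, offsets = list(c(0, 1)))
  expect_equal(unname(fv[["o0_1.contrast"]]), 0)
  expect_equal(unname(fv[["o0_1.energy"]]), 0.5)
})

test_that("GLCM on a constant patch is the single-cell matrix", {
  fv <- glcm_features(matrix(0.3, 8, 8), levels = 8)
  for (off in c("o0_1", "o1_0", "o1_1", "o1_-1")) {
    expect_equal(unname(fv[[paste0(off, ".contrast")]]), 0)
    expect_equal(unname(fv[[paste0(off, ".energy")]]), 1)
    expect_equal(unname(fv[[paste0(off, ".homogeneity")]]), 1)
  }
})

test_that("GLCM matrices equal the brute-force pair-count oracle", {
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1), c(2, -1))
  for (s in 1:10) {
    set.seed(s)
    q <- matrix(sample(0:3, 16 * 16, replace = TRUE), 16)
    for (off in offsets) {
      expect_equal(cystct:::glcm_matrix(q, off, 4), oracle_glcm(q, off, 4))
    }
  }
  expect_error(glcm_features(matrix(0.5, 3, 3), offsets = list(c(0, 5))),
               class = "cystct_offset_error")
})

test_that("LBP codes equal scalar recomputation with bilinear sampling", {
  for (s in 1:5) {
    set.seed(s)
    patch <- matrix(runif(64), 8)
    expect_equal(cystct:::lbp_codes(patch, 8, 1), oracle_lbp_codes(patch, 8, 1))
  }
  # all-equal neighbourhood: every code is 2^8 - 1
  h <- lbp_features(matrix(1, 8, 8), P = 8, R = 1, bins = 256)
  expect_equal(unname(h[256]), 1)
  expect_equal(sum(h), 1)
  set.seed(9)
  expect_equal(sum(lbp_features(matrix(runif(100), 10), bins = 32)), 1)
  expect_error(lbp_features(matrix(1, 3, 3), P = 8, R = 2),
               class = "cystct_size_error")
})

test_that("HOG responds to orientation and vanishes on flat input", {
  expect_true(all(hog_features(matrix(2, 32, 32)) == 0))
  set.seed(1)
  p <- matrix(runif(40 * 30), 40)
  expect_identical(hog_features(p), hog_features(p))
  # vertical stripes -> horizontal gradients -> mass in orientation bin 1
  stripes <- matrix(rep(c(0, 0, 0, 0, 1, 1, 1, 1), length.out = 64 * 64), 64, byrow = TRUE)
  fv <- hog_features(stripes, cell_size = 8, block_size = 2, bins = 9, resize_to = 64)
  by_bin <- tapply(fv, rep(1:9, times = length(fv) / 9), sum)
  expect_equal(unname(which.max(by_bin)), 1)
  # fixed length per config, independent of input size
  expect_equal(length(hog_features(matrix(runif(100), 10))),
               length(hog_features(matrix(runif(2500), 50))))
  expect_equal(length(fv), 7 * 7 * 2 * 2 * 9)
})

test_that("Gabor bank peaks at the matched frequency and orientation", {
  fv0 <- gabor_features(matrix(1, 20, 20))
  sds <- fv0[seq(2, length(fv0), 2)]
  expect_true(all(sds == 0))
  expect_equal(length(fv0), 2 * 4 * 4)
  # grating at f = 0.2, theta = 0 (variation along columns)
  n <- 48
  grating <- outer(1:n, 1:n, function(r, c) sin(2 * pi * 0.2 * c))
  fv <- gabor_features(grating)
  means <- matrix(fv[seq(1, length(fv), 2)], 4, 4, byrow = TRUE)  # freq x orient
  peak <- which(means == max(means), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(2, 1))   # frequency 0.2, orientation 0
  expect_error(gabor_features(matrix(1, 8, 8), frequencies = numeric(0)),
               class = "cystct_param_error")
})

test_that("Haar level-1 energies match the hand transform on a 2x2 patch", {
  a <- 3; b <- 7; cc <- 2; d <- 9
  patch <- matrix(c(a, cc, b, d), 2)   # rows (a, b), (c, d)
  fv <- wavelet_features(patch, levels = 1)
  expect_equal(unname(fv[["L1lh_energy"]]), ((a - b + cc - d) / 2)^2)
  expect_equal(unname(fv[["L1hl_energy"]]), ((a + b - cc - d) / 2)^2)
  expect_equal(unname(fv[["L1hh_energy"]]), ((a - b - cc + d) / 2)^2)
  expect_equal(unname(fv[["L1ll_energy"]]), ((a + b + cc + d) / 2)^2)
})

test_that("Haar decomposition is orthonormal (Parseval) and flat-silent", {
  fvc <- wavelet_features(matrix(4, 16, 16), levels = 2)
  expect_true(all(fvc[grep("(lh|hl|hh)_energy", names(fvc))] == 0))
  set.seed(2)
  x <- matrix(rnorm(16 * 16), 16)
  fv <- wavelet_features(x, levels = 2)
  nel <- c(L1 = 8 * 8, L2 = 4 * 4)
  total <- sum(fv[c("L1lh_energy", "L1hl_energy", "L1hh_energy")]) * nel["L1"] +
    sum(fv[c("L2lh_energy", "L2hl_energy", "L2hh_energy", "L2ll_energy")]) * nel["L2"]
  expect_equal(unname(total), sum(x^2), tolerance = 1e-10)
  expect_error(wavelet_features(matrix(1, 2, 2), levels = 3),
               class = "cystct_size_error")
  expect_error(wavelet_features(x, wavelet = "db4"), class = "cystct_param_error")
})

test_that("every extractor yields a constant-length finite descriptor", {
  set.seed(5)
  sizes <- list(c(18, 25), c(33, 33), c(60, 41))
  for (m in c("glcm", "lbp", "hog", "gabor", "wavelet")) {
    lens <- vapply(sizes, function(sz) {
      length(texture_features(matrix(runif(prod(sz)), sz[1]), method = m))
    }, 0L)
    expect_equal(length(unique(lens)), 1, info = m)
  }
})
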