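# Internal helpers shared across modules: classed errors, seeded evaluation,
# small image primitives (2-D convolution, bilinear resize).

cyst_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    list(message = msg, call = call),
    class = c(class, "cystct_error", "error", "condition")
  ))
}

#' @noRd
check_matrix <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    cyst_error(sprintf("`%s` must be a numeric matrix", name), "cystct_input_error")
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG state; the caller's RNG stream is
# untouched, so seeded operations compose without interfering.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' One experiment-level seed fans out to per-stage seeds (phantom generation,
#' splitting, classifier fitting, ...) by hashing the stage name, so any stage
#' can be re-run in isolation and still reproduce its stream.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483647)
}

# 'same'-size 2-D cross-correlation with replicate or zero padding, done as a
# shift-and-add over kernel taps (vectorised; fast for the small kernels used
# here).
conv2same <- function(x, k, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  kr <- nrow(k); kc <- ncol(k)
  cr <- (kr - 1L) %/% 2L; cc <- (kc - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  if (nr < kr || nc < kc) {
    cyst_error("image smaller than the convolution kernel", "cystct_size_error")
  }
  # pad
  ri <- c(rep(1L, cr), seq_len(nr), rep(nr, kr - 1L - cr))
  ci <- c(rep(1L, cc), seq_len(nc), rep(nc, kc - 1L - cc))
  xp <- x[ri, ci, drop = FALSE]
  if (pad == "zero") {
    xp[c(seq_len(cr), nr + cr + seq_len(kr - 1L - cr)), ] <- 0
    xp[, c(seq_len(cc), nc + cc + seq_len(kc - 1L - cc))] <- 0
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * xp[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Bilinear resize to out_r x out_c; pixel centres aligned as in standard
# image resampling (half-pixel convention).
bilinear_resize <- function(x, out_r, out_c) {
  check_matrix(x, "patch")
  nr <- nrow(x); nc <- ncol(x)
  if (out_r < 1 || out_c < 1) cyst_error("non-positive output size", "cystct_size_error")
  if (nr == out_r && nc == out_c) return(x)
  sr <- nr / out_r; sc <- nc / out_c
  rf <- pmin(pmax((seq_len(out_r) - 0.5) * sr - 0.5, 0), nr - 1)
  cf <- pmin(pmax((seq_len(out_c) - 0.5) * sc - 0.5, 0), nc - 1)
  r0 <- floor(rf); c0 <- floor(cf)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  wr <- rf - r0; wc <- cf - c0
  a <- x[r0 + 1, c0 + 1, drop = FALSE]; b <- x[r0 + 1, c1 + 1, drop = FALSE]
  d <- x[r1 + 1, c0 + 1, drop = FALSE]; e <- x[r1 + 1, c1 + 1, drop = FALSE]
  wrm <- matrix(wr, out_r, out_c); wcm <- matrix(wc, out_r, out_c, byrow = TRUE)
  (1 - wrm) * ((1 - wcm) * a + wcm * b) + wrm * ((1 - wcm) * d + wcm * e)
}
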