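# Convolutional feature extraction. The network is used strictly as a fixed
# feature extractor: a forward pass to a global-average-pooling layer whose
# output is the image descriptor. Weights are drawn once from a seeded
# He-scaled Gaussian, which keeps the whole pipeline reproducible offline;
# no training or fine-tuning happens anywhere in the package (classification
# is learned downstream, on the extracted features).
#
# Backends:
#   tiny_cnn    - small 3-conv stack, 64-d output; fast enough for routine
#                 test runs.
#   resnet_pool - residual conv stack whose global pooling emits the
#                 2048-d descriptor length familiar from ResNet-style
#                 backbones; heavier, same contract.
#   alexnet_pool is reserved but not implemented.

#' Deep feature-extractor configuration
#'
#' @param backend `"tiny_cnn"` (64-d) or `"resnet_pool"` (2048-d);
#'   `"alexnet_pool"` is reserved and raises an availability error.
#' @param input_size square input side in pixels; defaults to 32 for
#'   `tiny_cnn`, 64 for `resnet_pool`.
#' @param weights `"random"` (seeded, offline) — `"pretrained"` is not
#'   shipped and raises an availability error.
#' @param weight_seed integer seed for the weight draw.
#' @return A list of class `"extractor_config"` with the resolved
#'   `feature_length`.
#' @export
extractor_config <- function(backend = c("tiny_cnn", "resnet_pool", "alexnet_pool"),
                             input_size = NULL,
                             weights = c("random", "pretrained"),
                             weight_seed = 1L) {
  backend <- match.arg(backend)
  weights <- match.arg(weights)
  if (backend == "alexnet_pool") {
    cyst_error("backend \"alexnet_pool\" is not available; use \"tiny_cnn\" or \"resnet_pool\", or a texture extractor",
               "cystct_backend_error")
  }
  if (weights == "pretrained") {
    cyst_error("pretrained weights are not shipped; use weights = \"random\" (seeded) or a texture extractor",
               "cystct_backend_error")
  }
  if (is.null(input_size)) input_size <- if (backend == "tiny_cnn") 32L else 64L
  if (input_size <= 0) cyst_error("input_size must be > 0", "cystct_param_error")
  structure(list(backend = backend, input_size = as.integer(input_size),
                 weights = weights, weight_seed = as.integer(weight_seed),
                 feature_length = if (backend == "tiny_cnn") 64L else 2048L),
            class = "extractor_config")
}

#' Resize and standardise a multichannel image for the CNN
#'
#' Each channel is bilinearly resized to `input_size` square (aspect ratio
#' not preserved) and standardised to zero mean / unit SD; a zero-variance
#' channel becomes all zeros.
#'
#' @param mc a [assemble_multichannel()] result, or a list of 3 matrices.
#' @param input_size square side in pixels.
#' @return Array of shape `c(input_size, input_size, 3)`.
#' @export
prepare_input <- function(mc, input_size = 32L) {
  planes <- mc[c("windowed", "edges", "gradient")]
  if (any(vapply(planes, is.null, TRUE))) {
    cyst_error("input must have windowed/edges/gradient channels", "cystct_input_error")
  }
  if (length(planes$windowed) == 0) cyst_error("zero-area input", "cystct_size_error")
  out <- array(0, c(input_size, input_size, 3))
  for (i in 1:3) {
    x <- bilinear_resize(planes[[i]], input_size, input_size)
    s <- stats::sd(as.vector(x))
    out[, , i] <- if (s > 0) (x - mean(x)) / s else 0
  }
  out
}

# --- minimal conv-net primitives (inference only) -------------------------

he_weights <- function(n_out, n_in, k) {
  sd <- sqrt(2 / (n_in * k * k))
  array(stats::rnorm(n_out * n_in * k * k, 0, sd), c(k, k, n_in, n_out))
}

conv_layer <- function(x, w) {   # x: (r, c, n_in); w: (k, k, n_in, n_out)
  n_out <- dim(w)[4]; n_in <- dim(w)[3]
  out <- array(0, c(dim(x)[1], dim(x)[2], n_out))
  for (o in seq_len(n_out)) {
    acc <- matrix(0, dim(x)[1], dim(x)[2])
    for (i in seq_len(n_in)) {
      acc <- acc + conv2same(x[, , i], w[, , i, o], pad = "zero")
    }
    out[, , o] <- acc
  }
  out
}

conv1x1 <- function(x, W) {      # W: (n_in, n_out); pointwise projection
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3]) %*% W
  array(m, c(d[1], d[2], ncol(W)))
}

relu <- function(x) pmax(x, 0)

pool2 <- function(x) {           # 2x2 mean pooling
  d <- dim(x)
  nr <- d[1] %/% 2; nc <- d[2] %/% 2
  out <- array(0, c(nr, nc, d[3]))
  for (i in seq_len(d[3])) {
    p <- x[seq_len(2 * nr), seq_len(2 * nc), i]
    out[, , i] <- (p[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2)] +
                   p[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2)] +
                   p[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2)] +
                   p[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2)]) / 4
  }
  out
}

global_avg_pool <- function(x) apply(x, 3, mean)

make_network <- function(config) {
  with_seed(config$weight_seed, {
    if (config$backend == "tiny_cnn") {
      list(
        w1 = he_weights(8, 3, 3),
        w2 = he_weights(16, 8, 3),
        proj = matrix(stats::rnorm(16 * 64, 0, sqrt(2 / 16)), 16, 64)
      )
    } else {
      list(
        w1 = he_weights(16, 3, 3),
        r1a = he_weights(16, 16, 3), r1b = he_weights(16, 16, 3),
        w2 = he_weights(32, 16, 3),
        r2a = he_weights(32, 32, 3), r2b = he_weights(32, 32, 3),
        proj = matrix(stats::rnorm(32 * 2048, 0, sqrt(2 / 32)), 32, 2048)
      )
    }
  })
}

res_block <- function(x, wa, wb) relu(x + conv_layer(relu(conv_layer(x, wa)), wb))

forward_features <- function(x, net, backend) {
  if (backend == "tiny_cnn") {
    h <- pool2(relu(conv_layer(x, net$w1)))
    h <- pool2(relu(conv_layer(h, net$w2)))
    h <- relu(conv1x1(h, net$proj))
    global_avg_pool(h)
  } else {
    h <- pool2(relu(conv_layer(x, net$w1)))
    h <- res_block(h, net$r1a, net$r1b)
    h <- pool2(relu(conv_layer(h, net$w2)))
    h <- res_block(h, net$r2a, net$r2b)
    h <- relu(conv1x1(h, net$proj))
    global_avg_pool(h)
  }
}

#' Extract deep features from a multichannel image
#'
#' Forward pass of the configured (seeded, fixed-weight) conv-net up to
#' global average pooling. Deterministic for a given
#' `(backend, weight_seed, input)`.
#'
#' @param mc a [assemble_multichannel()] result.
#' @param config an [extractor_config()].
#' @param net optionally a prebuilt network (from repeated calls via
#'   [deep_feature_extractor()]) to avoid re-sampling weights per image.
#' @return Numeric feature vector of length `config$feature_length`.
#' @export
extract_deep_features <- function(mc, config = extractor_config(), net = NULL) {
  stopifnot(inherits(config, "extractor_config"))
  if (is.null(net)) net <- make_network(config)
  x <- prepare_input(mc, config$input_size)
  v <- forward_features(x, net, config$backend)
  feature_vector(v, config$backend)
}

#' Build a reusable deep feature extractor
#'
#' Samples the network weights once and returns a closure mapping a
#' multichannel image to its feature vector, so a dataset pass pays the
#' weight draw only once.
#'
#' @param config an [extractor_config()].
#' @return A function `f(mc) -> numeric vector`.
#' @export
deep_feature_extractor <- function(config = extractor_config()) {
  net <- make_network(config)
  function(mc) extract_deep_features(mc, config, net = net)
}
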