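# Conversion of an HU patch into the three-channel image the feature
# extractors consume: (1) display-windowed grayscale in [0,1]; (2) binary
# Canny edge map of the windowed plane; (3) Sobel gradient magnitude of the
# windowed plane, max-normalised to [0,1]. Channel order is fixed because
# CNN inputs are order-sensitive.

#' CT display window
#'
#' Maps the HU interval `[level - width/2, level + width/2]` linearly to
#' `[0, 1]`. The default is the standard soft-tissue abdomen window
#' (WL 40 / WW 400 HU).
#'
#' @param level window level (centre), HU.
#' @param width window width, HU (> 0).
#' @return A list of class `"window_spec"`.
#' @export
window_spec <- function(level = 40, width = 400) {
  if (width <= 0) cyst_error("window width must be > 0", "cystct_param_error")
  structure(list(level = level, width = width), class = "window_spec")
}

#' Canny edge-detector parameters
#'
#' @param sigma Gaussian smoothing SD in pixels (> 0).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 <= low <= high <= 1`.
#' @return A list of class `"canny_params"`.
#' @export
canny_params <- function(sigma = 1.0, low = 0.1, high = 0.2) {
  if (sigma <= 0) cyst_error("sigma must be > 0", "cystct_param_error")
  if (low < 0 || high > 1 || low > high) {
    cyst_error("need 0 <= low <= high <= 1", "cystct_param_error")
  }
  structure(list(sigma = sigma, low = low, high = high), class = "canny_params")
}

#' Apply a display window to an HU patch
#'
#' @param patch HU matrix.
#' @param spec a [window_spec()].
#' @return Matrix in `[0, 1]`, clamped outside the window; monotone
#'   non-decreasing in HU.
#' @export
window_image <- function(patch, spec = window_spec()) {
  check_matrix(patch, "patch")
  stopifnot(inherits(spec, "window_spec"))
  lo <- spec$level - spec$width / 2
  pmin(pmax((patch - lo) / spec$width, 0), 1)
}

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)  # d/dcol
sobel_y <- t(sobel_x)                                                # d/drow

#' Sobel gradient magnitude, max-normalised
#'
#' Per-pixel Euclidean norm of the 3x3 Sobel derivatives, rescaled to
#' `[0, 1]` by its maximum (an all-zero plane stays all-zero).
#'
#' @param plane numeric matrix, at least 3x3.
#' @return Matrix in `[0, 1]`.
#' @export
gradient_magnitude <- function(plane) {
  check_matrix(plane, "plane")
  if (nrow(plane) < 3 || ncol(plane) < 3) {
    cyst_error("plane smaller than the 3x3 Sobel operator", "cystct_size_error")
  }
  gx <- conv2same(plane, sobel_x)
  gy <- conv2same(plane, sobel_y)
  mag <- sqrt(gx^2 + gy^2)
  m <- max(mag)
  if (m > 0) mag / m else mag
}

#' Canny edge detection
#'
#' The standard four stages: Gaussian smoothing, Sobel gradient,
#' non-maximum suppression along the quantised gradient direction, and
#' double-threshold hysteresis (weak edges kept only if 8-connected to a
#' strong edge). Thresholds are fractions of the maximum smoothed gradient
#' magnitude.
#'
#' @param plane numeric matrix (typically the windowed channel).
#' @param params a [canny_params()].
#' @return Binary 0/1 matrix of edge pixels.
#' @export
canny_edges <- function(plane, params = canny_params()) {
  check_matrix(plane, "plane")
  stopifnot(inherits(params, "canny_params"))
  sm <- conv2same(plane, gaussian_kernel(params$sigma))
  gx <- conv2same(sm, sobel_x)
  gy <- conv2same(sm, sobel_y)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  # guard against pure floating-point residue on (near-)constant planes
  if (mmax <= 1e-8 * max(1, max(abs(sm)))) {
    return(matrix(0, nrow(plane), ncol(plane)))
  }

  # non-maximum suppression: compare each pixel with its two neighbours
  # along the gradient direction quantised to 0/45/90/135 degrees
  ang <- atan2(gy, gx)               # gx ~ d/dcol, gy ~ d/drow
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (floor((ang + pi / 8) / (pi / 4)) %% 4)  # 0:col,1:diag,2:row,3:anti-diag
  nr <- nrow(mag); nc <- ncol(mag)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mag
  shift <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  n1 <- matrix(0, nr, nc); n2 <- n1
  # sector 0: gradient along columns -> neighbours left/right
  sel <- sector == 0; n1[sel] <- shift(0, -1)[sel]; n2[sel] <- shift(0, 1)[sel]
  # sector 1: down-right / up-left diagonal
  sel <- sector == 1; n1[sel] <- shift(-1, -1)[sel]; n2[sel] <- shift(1, 1)[sel]
  # sector 2: gradient along rows -> neighbours up/down
  sel <- sector == 2; n1[sel] <- shift(-1, 0)[sel]; n2[sel] <- shift(1, 0)[sel]
  # sector 3: down-left / up-right diagonal
  sel <- sector == 3; n1[sel] <- shift(-1, 1)[sel]; n2[sel] <- shift(1, -1)[sel]
  keep <- (mag >= n1) & (mag >= n2)

  strong <- keep & (mag >= params$high * mmax)
  weak <- keep & (mag >= params$low * mmax) & !strong
  # hysteresis: grow strong edges through weak pixels (8-connectivity)
  cur <- strong
  repeat {
    p <- matrix(FALSE, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- cur
    dil <- p[1:nr, 1:nc] | p[1:nr, 2:(nc + 1)] | p[1:nr, 3:(nc + 2)] |
      p[2:(nr + 1), 1:nc] | p[2:(nr + 1), 3:(nc + 2)] |
      p[3:(nr + 2), 1:nc] | p[3:(nr + 2), 2:(nc + 1)] | p[3:(nr + 2), 3:(nc + 2)]
    nxt <- cur | (dil & weak)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  matrix(as.numeric(cur), nr, nc)
}

#' Assemble the three-channel image from an HU patch
#'
#' Channel 1 is the windowed patch, channel 2 the Canny edge map of channel
#' 1, channel 3 the max-normalised Sobel gradient magnitude of channel 1.
#' The gradient and edge channels are computed on the *windowed* plane, so
#' the display window also controls which HU contrasts can generate edges.
#'
#' @param patch HU matrix (at least 3x3).
#' @param window a [window_spec()].
#' @param canny a [canny_params()].
#' @return A list of class `"multichannel_image"` with matrices `windowed`,
#'   `edges`, `gradient`, all of the patch's shape.
#' @export
assemble_multichannel <- function(patch, window = window_spec(),
                                  canny = canny_params()) {
  check_matrix(patch, "patch")
  if (length(patch) == 0) cyst_error("empty patch", "cystct_size_error")
  w <- window_image(patch, window)
  structure(list(windowed = w,
                 edges = canny_edges(w, canny),
                 gradient = gradient_magnitude(w),
                 window = window, canny = canny),
            class = "multichannel_image")
}

#' @export
#' @method print multichannel_image
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image %dx%d: windowed [%.2f, %.2f], %d edge px, gradient max %.2f>\n",
              nrow(x$windowed), ncol(x$windowed), min(x$windowed), max(x$windowed),
              sum(x$edges), max(x$gradient)))
  invisible(x)
}
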