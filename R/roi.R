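# Lesion ROI handling. Two preprocessing paths feed the classifiers:
# (a) the manually outlined ROI image, with everything outside the outline
#     blanked to the bottom of the display window;
# (b) the semi-automatic rectangular patch: tight bounding box of the
#     outline, expanded 2 pixels outward so the patch holds the complete
#     lesion plus a thin band of surrounding tissue.
# Coordinates are 0-based and inclusive on both ends throughout the package,
# which makes "expand by 2 pixels" literal arithmetic on the box edges.

#' Bounding box constructor
#'
#' 0-based, inclusive-inclusive pixel coordinates.
#'
#' @param row_min,col_min,row_max,col_max integer pixel indices.
#' @return A list of class `"bounding_box"`.
#' @export
bounding_box <- function(row_min, col_min, row_max, col_max) {
  b <- lapply(list(row_min = row_min, col_min = col_min,
                   row_max = row_max, col_max = col_max), as.integer)
  if (b$row_min > b$row_max || b$col_min > b$col_max ||
      b$row_min < 0 || b$col_min < 0) {
    cyst_error("invalid bounding box extents", "cystct_box_error")
  }
  structure(b, class = "bounding_box")
}

#' @export
#' @method print bounding_box
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box rows %d..%d, cols %d..%d (0-based, inclusive)>\n",
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

#' Blank everything outside the ROI outline
#'
#' Returns the slice with pixels outside the mask replaced by `fill`. The
#' default fill is the lower bound of the standard soft-tissue window
#' (WL 40 / WW 400, i.e. -160 HU), rendering the surroundings as the darkest
#' displayable tissue.
#'
#' @param image HU matrix.
#' @param mask logical (or 0/1) matrix, same shape, nonempty.
#' @param fill HU value used outside the mask.
#' @return HU matrix of the same shape.
#' @export
masked_roi_image <- function(image, mask, fill = NULL) {
  check_matrix(image)
  if (!all(dim(image) == dim(mask))) {
    cyst_error("image and mask shapes differ", "cystct_shape_error")
  }
  mask <- mask > 0
  if (!any(mask)) cyst_error("empty ROI mask", "cystct_empty_mask_error")
  if (is.null(fill)) {
    w <- window_spec()
    fill <- w$level - w$width / 2
  }
  out <- image
  out[!mask] <- fill
  out
}

#' Tight bounding box of a mask
#'
#' @param mask logical (or 0/1) matrix with at least one positive pixel.
#' @return The smallest [bounding_box()] containing every mask pixel.
#' @export
tight_bounding_box <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) cyst_error("empty ROI mask", "cystct_empty_mask_error")
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  bounding_box(min(rows) - 1L, min(cols) - 1L, max(rows) - 1L, max(cols) - 1L)
}

#' Expand a bounding box outward, clipping at the image border
#'
#' @param box a [bounding_box()].
#' @param margin pixels added on every side (default 2).
#' @param image_shape `c(rows, cols)` of the parent image.
#' @return The expanded, clipped [bounding_box()].
#' @export
expand_box <- function(box, margin = 2L, image_shape) {
  stopifnot(inherits(box, "bounding_box"))
  if (margin < 0) cyst_error("margin must be >= 0", "cystct_param_error")
  nr <- image_shape[1]; nc <- image_shape[2]
  if (box$row_max >= nr || box$col_max >= nc) {
    cyst_error("box lies outside the image", "cystct_box_error")
  }
  bounding_box(max(box$row_min - margin, 0L), max(box$col_min - margin, 0L),
               min(box$row_max + margin, nr - 1L), min(box$col_max + margin, nc - 1L))
}

#' Extract the rectangular patch under a bounding box
#'
#' Values are copied unchanged (HU scale preserved); no resampling happens
#' at this stage.
#'
#' @param image HU matrix.
#' @param box a [bounding_box()] within the image.
#' @return Matrix of shape `(row_max - row_min + 1, col_max - col_min + 1)`.
#' @export
extract_patch <- function(image, box) {
  check_matrix(image)
  stopifnot(inherits(box, "bounding_box"))
  if (box$row_max >= nrow(image) || box$col_max >= ncol(image)) {
    cyst_error("box lies outside the image", "cystct_box_error")
  }
  image[(box$row_min + 1L):(box$row_max + 1L),
        (box$col_min + 1L):(box$col_max + 1L), drop = FALSE]
}
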