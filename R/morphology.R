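#' Structuring element
#'
#' Builds the `k x k` footprint used by [mask_dilate()] and [mask_erode()].
#' The elliptical footprint is the discretized ellipse inscribed in the
#' `k x k` box: cell `(i, j)` (offsets `di, dj` from the centre) belongs to
#' it iff its centre lies inside the axis-aligned ellipse with semi-axes
#' `r = (k - 1) / 2`, i.e. `(di/r)^2 + (dj/r)^2 <= 1`.  `k = 1` is the
#' single-cell footprint.
#'
#' @param k odd positive footprint size. The measurement pipeline uses
#'   `k = 11`.
#' @param shape `"ellipse"` (default) or `"rectangle"`.
#' @return an object of class `struct_element`: list with `shape`, `size`
#'   and the logical `k x k` `footprint` (origin always included).
#' @export
#' @examples
#' struct_element(11)$footprint
struct_element <- function(k = 11, shape = c("ellipse", "rectangle")) {
  shape <- match.arg(shape)
  k <- assert_odd(k)
  r <- (k - 1L) / 2
  d <- seq(-r, r)
  fp <- if (shape == "rectangle" || k == 1L) {
    matrix(TRUE, k, k)
  } else {
    outer(d, d, function(di, dj) (di / r)^2 + (dj / r)^2 <= 1)
  }
  structure(list(shape = shape, size = k, footprint = fp),
            class = "struct_element")
}

#' @export
print.struct_element <- function(x, ...) {
  cat(sprintf("<struct_element> %s %dx%d (%d cells)\n",
              x$shape, x$size, x$size, sum(x$footprint)))
  invisible(x)
}

# per-row half-widths of the footprint (for run-length morphology);
# rows with no cells get half-width NA
se_row_halfwidths <- function(se) {
  k <- se$size
  r <- (k - 1L) %/% 2L
  apply(se$footprint, 1, function(row) {
    j <- which(row)
    if (!length(j)) return(NA_integer_)
    max(abs(j - (r + 1L)))
  })
}

# horizontal binary window-OR / window-AND by running sums (zero padding)
run_window <- function(m, w, all_of = FALSE) {
  if (w == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  p <- cbind(matrix(0, nr, w), m, matrix(0, nr, w))
  cs <- t(apply(p, 1, cumsum))
  cs <- cbind(0, cs)
  j <- seq_len(nc) + w
  s <- cs[, j + w + 1, drop = FALSE] - cs[, j - w, drop = FALSE]
  if (all_of) s == (2 * w + 1) else s > 0
}

morph_binary <- function(mask, se, erode = FALSE) {
  assert_mask(mask)
  if (!inherits(se, "struct_element"))
    abort_ws("`se` must be a struct_element", "ws_config_error")
  if (se$size > min(dim(mask)))
    abort_ws("structuring element larger than the image", "ws_config_error")
  m <- mask > 0
  r <- (se$size - 1L) %/% 2L
  hw <- se_row_halfwidths(se)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(erode, nr, nc)   # OR-identity FALSE / AND-identity TRUE
  for (di in seq(-r, r)) {
    w <- hw[di + r + 1L]
    if (is.na(w)) next
    # shift rows by di with zero (background) padding outside the image
    shifted <- matrix(FALSE, nr, nc)
    src <- seq_len(nr) + di
    ok <- src >= 1 & src <= nr
    shifted[ok, ] <- m[src[ok], , drop = FALSE]
    row_op <- run_window(shifted, w, all_of = erode)
    if (erode) {
      if (any(!ok)) row_op[!ok, ] <- FALSE  # outside the image is background
      acc <- acc & row_op
    } else {
      acc <- acc | row_op
    }
  }
  matrix(ifelse(acc, 255, 0), nr, nc)
}

#' Morphological dilation of a binary mask
#'
#' A pixel is foreground in the output iff any pixel under the structuring
#' element centred there is foreground in the input.  The region outside
#' the image is treated as background.  Extensive (output contains the
#' input) because the origin belongs to every footprint.
#'
#' @param mask binary matrix (0/255).
#' @param se a [struct_element()]; default 11 x 11 ellipse.
#' @return dilated binary matrix.
#' @export
mask_dilate <- function(mask, se = struct_element(11)) {
  morph_binary(mask, se, erode = FALSE)
}

#' Morphological erosion of a binary mask
#'
#' A pixel is foreground in the output iff every pixel under the
#' structuring element centred there is foreground.  Outside the image is
#' background, so an all-foreground mask loses a border band.
#' Anti-extensive (output is contained in the input).
#'
#' @inheritParams mask_dilate
#' @return eroded binary matrix.
#' @export
mask_erode <- function(mask, se = struct_element(11)) {
  morph_binary(mask, se, erode = TRUE)
}

#' Morphological closing (dilation then erosion)
#'
#' Fills gaps smaller than the structuring element while approximately
#' preserving area; extensive and (away from the image border) idempotent.
#'
#' @inheritParams mask_dilate
#' @return closed binary matrix.
#' @export
mask_close <- function(mask, se = struct_element(11)) {
  mask_erode(mask_dilate(mask, se), se)
}
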