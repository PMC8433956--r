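#' Pixel-level raster operators
#'
#' Images are plain numeric matrices (grayscale, `height x width`, values
#' 0--255) or arrays (`height x width x 3` for RGB).  Binary masks are
#' matrices whose pixels are exactly 0 (background) or 255 (foreground).
#' All operators are deterministic: identical input bytes give identical
#' output bytes.
#'
#' @name raster-ops
NULL

#' Convert an RGB image to grayscale
#'
#' Applies the ITU-R BT.601 luma weights `0.299 R + 0.587 G + 0.114 B`,
#' rounds to the nearest integer (ties away from zero) and clips to
#' \[0, 255\].  A grayscale matrix passes through unchanged.
#'
#' @param img numeric array `h x w x 3` with 8-bit intensities in
#'   \[0, 255\], or an `h x w` grayscale matrix.
#' @return an `h x w` integer-valued matrix in \[0, 255\].
#' @export
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(px)  # 76
to_grayscale <- function(img) {
  if (is.matrix(img)) return(assert_gray(img))
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] < 3)
    abort_ws("`img` must be an h x w x 3 RGB array or a grayscale matrix",
             "ws_invalid_image")
  if (anyNA(img) || any(img < 0) || any(img > 255))
    abort_ws("`img` has intensities outside [0, 255]", "ws_invalid_image")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(pmin(255, pmax(0, round_half_away(g))), nrow = dim(img)[1])
}

# symmetric (edge-inclusive) reflection indices for padding by r
reflect_idx <- function(n, r) {
  if (r == 0) return(seq_len(n))
  c(r:1, seq_len(n), n:(n - r + 1))
}

#' Box blur
#'
#' Mean filter: each output pixel is the mean of the `k x k` window centred
#' on it, with the border handled by symmetric reflection, rounded to the
#' nearest integer.  `k = 1` is the identity; constant images are unchanged.
#'
#' @param img grayscale matrix (0--255).
#' @param k odd window size, `1 <= k <= min(dim(img))`. Default 19, the
#'   smoothing grid used by the measurement pipeline.
#' @return blurred grayscale matrix of the same dimensions.
#' @export
box_blur <- function(img, k = 19) {
  assert_gray(img)
  k <- assert_odd(k)
  if (k > min(dim(img)))
    abort_ws("`k` must not exceed the image dimensions", "ws_config_error")
  r <- (k - 1L) %/% 2L
  p <- img[reflect_idx(nrow(img), r), reflect_idx(ncol(img), r), drop = FALSE]
  # integral image: window sums in O(1) per pixel
  s <- apply(p, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- rbind(0, cbind(0, s))
  i1 <- seq_len(nrow(img)); j1 <- seq_len(ncol(img))
  win <- s[i1 + k, j1 + k, drop = FALSE] - s[i1, j1 + k, drop = FALSE] -
    s[i1 + k, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
  round_half_away(win / (k * k))
}

#' Otsu threshold and binarization
#'
#' Chooses the threshold `t` in 0..255 maximizing the between-class
#' variance `w0(t) w1(t) (mu0(t) - mu1(t))^2` of the 256-bin histogram
#' (classes: intensity `<= t` vs `> t`); ties broken toward the smallest
#' `t`.  The mask is 255 where intensity `> t` (bright pixels white), so a
#' dark wound on lighter skin is background until [invert_mask()] is
#' applied.
#'
#' @param img grayscale matrix (0--255).
#' @return list with `threshold` (integer) and `mask` (binary matrix).
#' @export
otsu_threshold <- function(img) {
  assert_gray(img)
  v <- floor(as.vector(img))
  if (min(v) == max(v))
    abort_ws("constant image: Otsu threshold is undefined (degenerate histogram)",
             "ws_degenerate_histogram")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  w0 <- cumsum(h) / n                     # P(class 0) for t = 0..255
  m  <- cumsum(h * (0:255)) / n
  mt <- m[256]
  w1 <- 1 - w0
  # between-class variance; undefined (0/0) where a class is empty
  num <- (mt * w0 - m)^2
  den <- w0 * w1
  crit <- ifelse(den > 0, num / den, -Inf)
  t <- which.max(crit) - 1L               # which.max takes the first maximum
  mask <- matrix(ifelse(img > t, 255, 0), nrow = nrow(img))
  list(threshold = as.integer(t), mask = mask)
}

#' Invert a binary mask
#'
#' Swaps 0 and 255 so that a dark lesion binarized to background becomes
#' foreground. Involutive: `invert_mask(invert_mask(m))` is `m`.
#'
#' @param mask binary matrix (values 0/255).
#' @return inverted binary matrix.
#' @export
invert_mask <- function(mask) {
  assert_mask(mask)
  255 - mask
}
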