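#' Canny edge detection
#'
#' Classic Canny: 3 x 3 Sobel gradients (replicate border), L1 gradient
#' magnitude, non-maximum suppression along the quantized gradient
#' direction (ties kept, so a perfectly symmetric step edge can be 2 px
#' wide), double thresholding and hysteresis (weak edge pixels are kept
#' only when 8-connected to a strong pixel).  In the measurement pipeline
#' the input is the closed binary mask, whose step edges have gradient
#' magnitude far above any mid-range threshold pair, so the defaults are
#' insensitive there.
#'
#' @param img grayscale or binary matrix (0--255).
#' @param low,high hysteresis thresholds on the L1 gradient magnitude,
#'   `0 < low < high`. Defaults 100 and 200.
#' @return binary edge mask (0/255).
#' @export
canny_edges <- function(img, low = 100, high = 200) {
  assert_gray(img)
  if (low <= 0 || low >= high)
    abort_ws("need 0 < low < high", "ws_config_error")
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(matrix(0, nr, nc))
  shift <- function(m, dy, dx) {  # replicate padding
    ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  gx <- (shift(img, -1, 1) + 2 * shift(img, 0, 1) + shift(img, 1, 1)) -
        (shift(img, -1, -1) + 2 * shift(img, 0, -1) + shift(img, 1, -1))
  gy <- (shift(img, 1, -1) + 2 * shift(img, 1, 0) + shift(img, 1, 1)) -
        (shift(img, -1, -1) + 2 * shift(img, -1, 0) + shift(img, -1, 1))
  mag <- abs(gx) + abs(gy)
  # quantize gradient direction to 4 sectors: 0 = E-W, 1 = NE-SW,
  # 2 = N-S, 3 = NW-SE
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  n1 <- matrix(0, nr, nc); n2 <- n1
  pick <- function(s, dy, dx, which) {
    sel <- sector == s
    sh <- shift(mag, dy, dx)
    if (which == 1) n1[sel] <<- sh[sel] else n2[sel] <<- sh[sel]
  }
  pick(0, 0,  1, 1); pick(0, 0, -1, 2)    # horizontal gradient
  pick(1, 1,  1, 1); pick(1, -1, -1, 2)   # 45 deg (y down): SE / NW
  pick(2, 1,  0, 1); pick(2, -1, 0, 2)    # vertical gradient
  pick(3, 1, -1, 1); pick(3, -1,  1, 2)   # 135 deg: SW / NE
  keep <- mag >= n1 & mag >= n2 & mag > 0
  # replicate-padded Sobel is unreliable on the outermost ring; matches
  # the convention of dropping the 1-px frame
  keep[c(1, nr), ] <- FALSE
  keep[, c(1, nc)] <- FALSE
  strong <- keep & mag > high
  weak <- keep & mag > low
  if (!any(strong)) return(matrix(0, nr, nc))
  lab <- cc_label_cpp(weak, 8L)
  keep_ids <- unique(lab$labels[strong])
  edges <- weak & matrix(lab$labels %in% keep_ids, nr, nc)
  matrix(ifelse(edges, 255, 0), nr, nc)
}
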