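#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 2.5 -> 3, -2.5 -> -3),
#' the convention needed to reproduce the reported measurement tables.
#' `base::round()` rounds half to even and cannot be used for the 2- and
#' 4-decimal reporting steps.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(2.5)    # 3
#' round_half_away(5.9775, 2)  # 5.98
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

abort_ws <- function(msg, class) {
  rlang::abort(msg, class = c(class, "woundsizer_error"))
}

#' @noRd
assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    abort_ws(sprintf("`%s` must be a numeric matrix (grayscale image)", arg),
             "ws_invalid_image")
  if (anyNA(img) || any(img < 0) || any(img > 255))
    abort_ws(sprintf("`%s` has intensities outside [0, 255]", arg),
             "ws_invalid_image")
  invisible(img)
}

#' @noRd
assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    abort_ws(sprintf("`%s` must be a numeric matrix", arg), "ws_invalid_mask")
  if (!all(mask == 0 | mask == 255))
    abort_ws(sprintf("`%s` is not binary: every pixel must be 0 or 255", arg),
             "ws_invalid_mask")
  invisible(mask)
}

#' @noRd
assert_odd <- function(k, arg = "k") {
  if (length(k) != 1 || is.na(k) || k < 1 || k %% 2 != 1)
    abort_ws(sprintf("`%s` must be a positive odd integer", arg),
             "ws_config_error")
  invisible(as.integer(k))
}
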