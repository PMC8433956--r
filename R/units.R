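#' Convert pixels to centimetres from DPI
#'
#' `value_cm = value_px * 2.54 / dpi` (1 inch = 2.54 cm), unrounded and
#' linear in `value_px`. Vectorized over `value_px`.
#'
#' @param value_px length in pixels (or area in px along one axis), >= 0.
#' @param dpi dots per inch along that axis, > 0.
#' @return length in centimetres.
#' @export
#' @examples
#' px_to_cm(300, 300)  # one inch = 2.54 cm
#' px_to_cm(706, 300)  # 5.9775...
px_to_cm <- function(value_px, dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1 || is.na(dpi) || dpi <= 0)
    abort_ws("`dpi` must be a single positive number", "ws_domain_error")
  if (any(value_px < 0))
    abort_ws("`value_px` must be >= 0", "ws_domain_error")
  value_px * 2.54 / dpi
}

#' Wound measurement record
#'
#' Converts a wound area in px^2 to cm^2 by proportion of the image's
#' total physical area: the image width and height are converted with
#' [px_to_cm()] and rounded to 2 decimals (half away from zero) *before*
#' multiplying into the total area in cm^2, and the wound area is the
#' wound pixel fraction of that total, reported to 4 decimals.  Rounding
#' before multiplication is deliberate: it is the reporting convention of
#' the measurement tables this implementation reproduces.
#'
#' When `width_px` is not given it is derived as
#' `total_area_px / height_px`, which keeps the conversion consistent
#' with the stated total pixel area even when a separately printed width
#' disagrees with it.
#'
#' @param wound_area_px wound area in px^2, `0 <= wound_area_px <=
#'   total_area_px`.
#' @param total_area_px total image area in px^2 (> 0).
#' @param height_px image height in pixels.
#' @param dpi_x,dpi_y horizontal / vertical dots per inch (`dpi_y`
#'   defaults to `dpi_x`).
#' @param width_px image width in pixels; default derived from
#'   `total_area_px / height_px`.
#' @return a one-row tibble of class `wound_measurement` with columns
#'   `wound_area_px`, `total_area_px`, `width_px`, `height_px`,
#'   `width_cm`, `height_cm`, `total_area_cm2`, `wound_area_cm2`,
#'   `dpi_x`, `dpi_y`.
#' @export
#' @examples
#' measure_wound(54746.5, 749772, 706, 300)
measure_wound <- function(wound_area_px, total_area_px, height_px,
                          dpi_x, dpi_y = dpi_x, width_px = NULL) {
  if (total_area_px <= 0)
    abort_ws("`total_area_px` must be > 0", "ws_domain_error")
  if (wound_area_px < 0 || wound_area_px > total_area_px)
    abort_ws("need 0 <= wound_area_px <= total_area_px", "ws_domain_error")
  if (is.null(width_px)) width_px <- total_area_px / height_px
  width_cm  <- round_half_away(px_to_cm(width_px, dpi_x), 2)
  height_cm <- round_half_away(px_to_cm(height_px, dpi_y), 2)
  total_area_cm2 <- width_cm * height_cm
  wound_area_cm2 <- round_half_away(
    wound_area_px / total_area_px * total_area_cm2, 4)
  out <- tibble::tibble(
    wound_area_px = wound_area_px, total_area_px = total_area_px,
    width_px = width_px, height_px = height_px,
    width_cm = width_cm, height_cm = height_cm,
    total_area_cm2 = total_area_cm2, wound_area_cm2 = wound_area_cm2,
    dpi_x = dpi_x, dpi_y = dpi_y)
  class(out) <- c("wound_measurement", class(out))
  out
}
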