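#' Cross-device comparison of wound-area measurements
#'
#' Compares paired wound areas measured for the same photographs on two
#' platforms (a reference device and a test device): per-image
#' differences, the mean absolute percentage error (MAE), and a
#' multiplicative MAE adjustment of the test series.
#'
#' Formulas (per pair, rounding half away from zero):
#' `diff_cm2 = round2(test - ref)`,
#' `diff_pct = round1(100 * (test - ref) / ref)`,
#' `mae_pct = mean(|diff_pct|)` (kept unrounded internally, reported to
#' 1 decimal).
#'
#' @param data a data frame with columns `label`, `ref_cm2` (reference
#'   device, all > 0) and `test_cm2` (>= 0).
#' @return an object of class `wound_calibration`: list with
#'   `comparison` (tibble `label`, `ref_cm2`, `test_cm2`, `diff_cm2`,
#'   `diff_pct`), `mae_pct` and `mae_fraction` (= `mae_pct / 100`).
#' @export
#' @examples
#' compare_measurements(device_comparison())
compare_measurements <- function(data) {
  need <- c("label", "ref_cm2", "test_cm2")
  if (!all(need %in% names(data)))
    abort_ws("`data` needs columns label, ref_cm2, test_cm2",
             "ws_domain_error")
  if (nrow(data) == 0)
    abort_ws("`data` must have at least one row", "ws_domain_error")
  if (any(data$ref_cm2 <= 0))
    abort_ws("all `ref_cm2` must be > 0", "ws_domain_error")
  cmp <- tibble::tibble(
    label = data$label, ref_cm2 = data$ref_cm2, test_cm2 = data$test_cm2,
    diff_cm2 = round_half_away(data$test_cm2 - data$ref_cm2, 2),
    diff_pct = round_half_away(
      100 * (data$test_cm2 - data$ref_cm2) / data$ref_cm2, 1))
  mae <- mean(abs(cmp$diff_pct))
  structure(list(comparison = cmp, mae_pct = mae, mae_fraction = mae / 100),
            class = "wound_calibration")
}

#' Adjust test-device measurements by an MAE fraction
#'
#' Applies the multiplicative calibration
#' `adjusted_cm2 = round2(test_cm2 * (1 + mae_fraction))` and recomputes
#' the differences of the adjusted values against the reference with the
#' same formulas as [compare_measurements()]. `mae_fraction = 0` is the
#' identity on the test values.
#'
#' @inheritParams compare_measurements
#' @param mae_fraction non-negative calibration factor, e.g.
#'   `compare_measurements(data)$mae_fraction`.
#' @return a tibble `label`, `ref_cm2`, `test_cm2`, `adjusted_cm2`,
#'   `diff_cm2`, `diff_pct` (differences of adjusted vs reference).
#' @export
#' @examples
#' adjust_measurements(device_comparison(), 0.347)
adjust_measurements <- function(data, mae_fraction) {
  if (mae_fraction < 0)
    abort_ws("`mae_fraction` must be >= 0", "ws_domain_error")
  cmp <- compare_measurements(data)$comparison
  adj <- round_half_away(cmp$test_cm2 * (1 + mae_fraction), 2)
  tibble::tibble(
    label = cmp$label, ref_cm2 = cmp$ref_cm2, test_cm2 = cmp$test_cm2,
    adjusted_cm2 = adj,
    diff_cm2 = round_half_away(adj - cmp$ref_cm2, 2),
    diff_pct = round_half_away(100 * (adj - cmp$ref_cm2) / cmp$ref_cm2, 1))
}

#' Published desktop-vs-mobile wound-area pairs
#'
#' The ten paired wound areas (cm^2) measured for the same photographs by
#' the desktop implementation (reference) and the mobile implementation
#' (test) of the measurement method, shipped as the calibration example
#' data set.
#'
#' @return tibble with columns `label`, `ref_cm2`, `test_cm2`.
#' @export
device_comparison <- function() {
  path <- system.file("extdata", "device_comparison.csv",
                      package = "woundsizer", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' @export
print.wound_calibration <- function(x, ...) {
  cat("<wound_calibration>\n")
  print(x$comparison)
  cat(sprintf("MAE: %.1f%%\n", x$mae_pct))
  invisible(x)
}

#' @rdname compare_measurements
#' @param x a `wound_calibration` object.
#' @param ... unused.
#' @export
tidy.wound_calibration <- function(x, ...) x$comparison

#' @rdname compare_measurements
#' @export
glance.wound_calibration <- function(x, ...) {
  tibble::tibble(n = nrow(x$comparison), mae_pct = x$mae_pct,
                 mae_fraction = x$mae_fraction)
}
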