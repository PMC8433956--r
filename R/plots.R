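#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# long data frame of one stage image, optionally downsampled for plotting
image_df <- function(img, stage, max_px = 160000) {
  step <- max(1L, ceiling(sqrt(length(img) / max_px)))
  ri <- seq(1, nrow(img), by = step)
  ci <- seq(1, ncol(img), by = step)
  sub <- img[ri, ci, drop = FALSE]
  tibble::tibble(stage = stage,
                 x = rep(ci - 1L, each = length(ri)),
                 y = rep(ri - 1L, length(ci)),
                 value = as.vector(sub))
}

#' Plot the pipeline stage images
#'
#' Facets the nine intermediate images (a--i) of a pipeline run, large
#' images downsampled for display.
#'
#' @param object a `wound_pipeline` result with intermediates.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wound_pipeline <- function(object, ...) {
  if (!length(object$intermediates))
    abort_ws("pipeline was run with keep_intermediates = FALSE",
             "ws_config_error")
  df <- dplyr::bind_rows(purrr::imap(object$intermediates, image_df))
  df$stage <- factor(df$stage, levels = names(object$intermediates))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::facet_wrap(~stage) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("wound area: %.4f cm^2",
                                  object$measurement$wound_area_cm2)) +
    ggplot2::theme_minimal()
}

#' Plot a cross-device calibration
#'
#' Diverging bars of the per-image percent difference between test and
#' reference device, with the MAE annotated.
#'
#' @param object a `wound_calibration` from [compare_measurements()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wound_calibration <- function(object, ...) {
  df <- object$comparison
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$diff_pct)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "difference vs reference (%)",
                  subtitle = sprintf("MAE %.1f%%", object$mae_pct)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
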