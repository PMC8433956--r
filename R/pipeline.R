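#' Pipeline configuration
#'
#' Parameters of the wound-measurement pipeline, with the defaults the
#' method was described with: a 19 x 19 box blur, an 11 x 11 elliptical
#' structuring element for closing and for the post-Canny edge dilation,
#' and a minimum contour area of 50 px^2.
#'
#' @param blur_kernel odd box-blur window (default 19).
#' @param morph_kernel odd structuring-element size for the closing
#'   (default 11).
#' @param morph_shape `"ellipse"` (default) or `"rectangle"`.
#' @param min_contour_area contours below this area (px^2) are discarded,
#'   both right after binarization and after edge dilation (default 50).
#' @param canny_low,canny_high hysteresis thresholds (defaults 100/200;
#'   on a binary mask any mid-range pair finds the same boundary).
#' @param edge_dilate_kernel odd size of the ellipse used to dilate the
#'   Canny edges (default 11, reusing the closing kernel size).
#' @param mean_area_filter keep only contours with at least the mean
#'   contour area in the final set (default `TRUE`).
#' @param min_class_separation minimum distance in gray levels between
#'   the two Otsu class means of the blurred image for a wound to be
#'   considered present (default 20). Thresholding presumes a bimodal
#'   histogram; on a lesion-free photograph the blur flattens sensor
#'   noise to a near-constant image whose Otsu split separates the class
#'   means by only a gray level or two, so anything below this guard is
#'   reported as "no wound detected" instead of segmenting noise. The
#'   default sits far above blurred sensor noise and far below the
#'   several-tens-of-levels contrast a real lesion has against skin.
#' @param dpi_override optional DPI used when the image file carries no
#'   resolution metadata.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(blur_kernel = 19, morph_kernel = 11,
                            morph_shape = c("ellipse", "rectangle"),
                            min_contour_area = 50,
                            canny_low = 100, canny_high = 200,
                            edge_dilate_kernel = 11,
                            mean_area_filter = TRUE,
                            min_class_separation = 20,
                            dpi_override = NULL) {
  morph_shape <- match.arg(morph_shape)
  assert_odd(blur_kernel, "blur_kernel")
  assert_odd(morph_kernel, "morph_kernel")
  assert_odd(edge_dilate_kernel, "edge_dilate_kernel")
  if (min_contour_area < 0)
    abort_ws("`min_contour_area` must be >= 0", "ws_config_error")
  if (canny_low <= 0 || canny_low >= canny_high)
    abort_ws("need 0 < canny_low < canny_high", "ws_config_error")
  structure(list(blur_kernel = as.integer(blur_kernel),
                 morph_kernel = as.integer(morph_kernel),
                 morph_shape = morph_shape,
                 min_contour_area = min_contour_area,
                 canny_low = canny_low, canny_high = canny_high,
                 edge_dilate_kernel = as.integer(edge_dilate_kernel),
                 mean_area_filter = isTRUE(mean_area_filter),
                 min_class_separation = min_class_separation,
                 dpi_override = dpi_override),
            class = "pipeline_config")
}

#' Read a config file (flat key=value or JSON) into a pipeline_config
#'
#' @param path path to a JSON object or a `key=value` lines file whose
#'   keys are [pipeline_config()] argument names.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vals <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    kv <- strsplit(sub("#.*", "", txt[nzchar(trimws(txt))]), "=")
    kv <- kv[lengths(kv) == 2]
    stats::setNames(
      lapply(kv, function(p) utils::type.convert(trimws(p[2]), as.is = TRUE)),
      vapply(kv, function(p) trimws(p[1]), ""))
  }
  do.call(pipeline_config, vals)
}

#' Run the wound-measurement pipeline on one photograph
#'
#' Executes, in order: grayscale conversion (a), box blur (b), Otsu
#' binarization + inversion so the dark wound becomes white (c), contour
#' detection with removal of shapes below `min_contour_area` (d),
#' dilation (e) and erosion (f) with the elliptical structuring element,
#' Canny edge detection on the closed mask (g), dilation of the edges
#' (h), and a final contour pass -- discard below `min_contour_area`,
#' keep contours with at least the mean area, sum their shoelace areas --
#' whose kept regions form the final image (i).  The summed pixel area is
#' converted to cm^2 from the DPI metadata via [measure_wound()].
#'
#' Deterministic: identical input bytes give an identical result.  An
#' empty final contour set is reported as "no wound detected" with zero
#' areas, not an error.
#'
#' @param x a file path, or a list with `pixels` and `meta` as returned
#'   by [read_wound_image()] (or a raw pixel matrix/array if `meta` is
#'   supplied separately).
#' @param config a [pipeline_config()].
#' @param meta an [image_metadata()] row, required when `x` is a bare
#'   pixel grid.
#' @param keep_intermediates keep the nine stage images (default `TRUE`;
#'   turn off to save memory in batch runs).
#' @return an object of class `wound_pipeline`: list with `measurement`
#'   (a [measure_wound()] tibble row), `contours` (the final kept contour
#'   tibble), `all_contours` (stage-i contours before the mean filter),
#'   `intermediates` (named list `a` ... `i` of stage images), `log`
#'   (per-stage tibble of parameters and contour counts), `meta`,
#'   `config`, and `no_wound` (logical).
#' @export
run_pipeline <- function(x, config = pipeline_config(), meta = NULL,
                         keep_intermediates = TRUE) {
  if (is.character(x)) {
    img <- read_wound_image(x, dpi = config$dpi_override)
    pixels <- img$pixels; meta <- img$meta
  } else if (is.list(x) && !is.null(x$pixels)) {
    pixels <- x$pixels; meta <- x$meta
  } else {
    pixels <- x
  }
  if (is.null(meta))
    abort_ws("no image metadata: supply `meta` or a file with DPI",
             "ws_missing_dpi")
  se  <- struct_element(config$morph_kernel, config$morph_shape)
  se2 <- struct_element(config$edge_dilate_kernel, config$morph_shape)

  stages <- list()
  logs <- list()
  note <- function(stage, what, contours = NA_integer_) {
    logs[[length(logs) + 1L]] <<- tibble::tibble(
      stage = stage, operation = what, n_contours = contours)
  }

  a <- to_grayscale(pixels)
  note("a", "grayscale")
  b <- box_blur(a, config$blur_kernel)
  note("b", sprintf("box_blur k=%d", config$blur_kernel))
  ot <- tryCatch(otsu_threshold(b), ws_degenerate_histogram = function(e) NULL)
  low_contrast <- !is.null(ot) && {
    fg <- b > ot$threshold
    abs(mean(b[fg]) - mean(b[!fg])) < config$min_class_separation
  }
  if (is.null(ot) || low_contrast) {
    # constant or contrast-free image: nothing to segment, report no wound
    note("c", if (is.null(ot)) "degenerate histogram: no wound"
              else sprintf("class separation < %g: no wound",
                           config$min_class_separation))
    empty <- find_contours(matrix(0, 1, 1))[0, ]
    zero <- matrix(0, nrow(a), ncol(a))
    m <- measure_wound(0, meta$width_px * meta$height_px, meta$height_px,
                       meta$dpi_x, meta$dpi_y, width_px = meta$width_px)
    stages <- if (keep_intermediates)
      list(a = a, b = b, c = zero, d = zero, e = zero, f = zero, g = zero,
           h = zero, i = zero) else list()
    return(structure(list(measurement = m, contours = empty,
                          all_contours = empty, intermediates = stages,
                          log = dplyr::bind_rows(logs), meta = meta,
                          config = config, no_wound = TRUE),
                     class = "wound_pipeline"))
  }
  cc <- invert_mask(ot$mask)
  note("c", sprintf("otsu t=%d + invert", ot$threshold))
  d_contours <- find_contours(cc)
  d <- remove_small_shapes(cc, config$min_contour_area)
  note("d", sprintf("remove_small_shapes < %g", config$min_contour_area),
       nrow(d_contours))
  e <- mask_dilate(d, se)
  note("e", sprintf("dilate %s %dx%d", se$shape, se$size, se$size))
  f <- mask_erode(e, se)
  note("f", sprintf("erode %s %dx%d", se$shape, se$size, se$size))
  g <- canny_edges(f, config$canny_low, config$canny_high)
  note("g", sprintf("canny %g/%g", config$canny_low, config$canny_high))
  h <- mask_dilate(g, se2)
  note("h", sprintf("dilate edges %dx%d", se2$size, se2$size))
  cs <- find_contours(h)
  cs <- cs[cs$area_px >= config$min_contour_area, , drop = FALSE]
  kept <- if (config$mean_area_filter) filter_by_mean_area(cs) else cs
  note("i", sprintf("final contours: %d kept of %d", nrow(kept), nrow(cs)),
       nrow(kept))
  i_img <- render_final(h, kept)

  wound_px <- total_area(kept)
  total_px <- meta$width_px * meta$height_px
  no_wound <- nrow(kept) == 0
  m <- measure_wound(min(wound_px, total_px), total_px, meta$height_px,
                     meta$dpi_x, meta$dpi_y, width_px = meta$width_px)
  if (keep_intermediates)
    stages <- list(a = a, b = b, c = cc, d = d, e = e, f = f, g = g,
                   h = h, i = i_img)
  structure(list(measurement = m, contours = kept, all_contours = cs,
                 intermediates = stages, log = dplyr::bind_rows(logs),
                 meta = meta, config = config, no_wound = no_wound),
            class = "wound_pipeline")
}

# stage-i image: foreground regions of `mask` that own a kept contour
render_final <- function(mask, kept) {
  if (nrow(kept) == 0) return(matrix(0, nrow(mask), ncol(mask)))
  lf <- cc_label_cpp(mask > 0, 8L)
  keep_ids <- unique(vapply(kept$points, function(p) {
    # a contour belongs to the fg component at (or next to) its first vertex
    r <- p[1, 2] + 1L; c <- p[1, 1] + 1L
    if (lf$labels[r, c] > 0) return(lf$labels[r, c])
    # hole contour: its first pixel is background; use the fg pixel above
    if (r > 1 && lf$labels[r - 1L, c] > 0) return(lf$labels[r - 1L, c])
    0L
  }, 0L))
  out <- matrix(0, nrow(mask), ncol(mask))
  out[matrix(lf$labels %in% setdiff(keep_ids, 0L), nrow(mask))] <- 255
  out
}

#' Save the nine pipeline stage images as PNG files
#'
#' Writes `step_a.png` ... `step_i.png` into `dir`.
#'
#' @param result a `wound_pipeline` object with intermediates.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
save_steps <- function(result, dir) {
  if (!length(result$intermediates))
    abort_ws("pipeline was run with keep_intermediates = FALSE",
             "ws_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(result$intermediates)) {
    p <- file.path(dir, sprintf("step_%s.png", nm))
    write_wound_image(p, result$intermediates[[nm]], result$meta)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.wound_pipeline <- function(x, ...) {
  m <- x$measurement
  cat("<wound_pipeline>\n")
  if (x$no_wound) cat("  no wound detected\n")
  cat(sprintf("  image: %d x %d px at %g x %g DPI\n",
              m$width_px, m$height_px, m$dpi_x, m$dpi_y))
  cat(sprintf("  wound area: %.1f px^2 = %.4f cm^2 (%d contours kept)\n",
              m$wound_area_px, m$wound_area_cm2, nrow(x$contours)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_pipeline
#' @param x a `wound_pipeline` object.
#' @param ... unused.
#' @export
tidy.wound_pipeline <- function(x, ...) {
  out <- x$measurement
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname run_pipeline
#' @export
glance.wound_pipeline <- function(x, ...) {
  tibble::tibble(wound_area_cm2 = x$measurement$wound_area_cm2,
                 wound_area_px = x$measurement$wound_area_px,
                 n_contours = nrow(x$contours),
                 no_wound = x$no_wound)
}
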