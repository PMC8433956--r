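#' Contour extraction and the contour-area filters
#'
#' Contours are the traced closed boundary polygons of connected
#' foreground regions (8-connected) and of their holes (4-connected
#' background regions not touching the image border), found by
#' Moore-neighbour border following in raster-scan discovery order.
#' Areas are shoelace polygon areas over the full traced vertex sequence,
#' in px^2; the traced boundary of a filled `n x n` square has area
#' `(n - 1)^2` (vertices run through pixel centres, so polygon area
#' undercounts pixel count by about half the perimeter).
#'
#' @name contours
NULL

#' Find all contours of a binary mask
#'
#' Returns outer boundaries of all 8-connected foreground regions and the
#' boundaries of their holes, as a flat list without hierarchy, ordered by
#' raster-scan discovery (the row-major position of each contour's first
#' pixel).
#'
#' @param mask binary matrix (0/255).
#' @return a tibble with one row per contour: `contour` (id), `type`
#'   (`"outer"` or `"hole"`), `n_points`, `area_px` (shoelace area), and
#'   `points` (list column of `n x 2` matrices of 0-based `(x, y)` pixel
#'   coordinates, x = column rightward, y = row downward). Zero rows for
#'   an empty foreground.
#' @export
find_contours <- function(mask) {
  assert_mask(mask)
  fg <- mask > 0
  out <- list(); starts <- integer()
  nr <- nrow(mask)
  lf <- cc_label_cpp(fg, 8L)
  if (lf$n > 0) {
    for (i in seq_len(lf$n)) {
      pts <- trace_region_cpp(lf$labels, i, lf$start_row[i], lf$start_col[i])
      out[[length(out) + 1L]] <- list(type = "outer", points = pts)
      starts <- c(starts, (lf$start_row[i] - 1L) * ncol(mask) + lf$start_col[i])
    }
  }
  lb <- cc_label_cpp(!fg, 4L)
  if (lb$n > 0) {
    for (i in seq_len(lb$n)) {
      if (lb$touches_border[i]) next           # outer background, not a hole
      pts <- trace_region_cpp(lb$labels, i, lb$start_row[i], lb$start_col[i])
      out[[length(out) + 1L]] <- list(type = "hole", points = pts)
      starts <- c(starts, (lb$start_row[i] - 1L) * ncol(mask) + lb$start_col[i])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(contour = integer(), type = character(),
                          n_points = integer(), area_px = numeric(),
                          points = list()))
  }
  ord <- order(starts)
  out <- out[ord]
  tibble::tibble(
    contour = seq_along(out),
    type = vapply(out, `[[`, "", "type"),
    n_points = vapply(out, function(o) nrow(o$points), 0L),
    area_px = vapply(out, function(o) contour_area(o$points), 0),
    points = lapply(out, `[[`, "points")
  )
}

#' Shoelace area of a contour polygon
#'
#' Absolute value of the signed (shoelace) polygon area over the ordered
#' vertex sequence, in px^2.  Degenerate contours (fewer than 3 distinct
#' points) have area 0.
#'
#' @param points `n x 2` matrix of `(x, y)` vertices (the polygon is
#'   closed implicitly).
#' @return non-negative area in px^2.
#' @export
#' @examples
#' contour_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
contour_area <- function(points) {
  if (is.null(points) || !is.matrix(points) || nrow(points) < 3) return(0)
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Remove small foreground regions
#'
#' Erases every 8-connected foreground region whose traced outer-contour
#' area is strictly smaller than `min_area` (painting its pixels
#' background). Idempotent; the output foreground is a subset of the
#' input's. Holes are left untouched.
#'
#' @param mask binary matrix (0/255).
#' @param min_area minimum outer-contour area in px^2 to survive
#'   (default 50, the pipeline's cutoff).
#' @return filtered binary matrix.
#' @export
remove_small_shapes <- function(mask, min_area = 50) {
  assert_mask(mask)
  if (min_area < 0)
    abort_ws("`min_area` must be >= 0", "ws_config_error")
  if (min_area == 0) return(mask)
  lf <- cc_label_cpp(mask > 0, 8L)
  if (lf$n == 0) return(mask)
  for (i in seq_len(lf$n)) {
    pts <- trace_region_cpp(lf$labels, i, lf$start_row[i], lf$start_col[i])
    if (contour_area(pts) < min_area) mask[lf$labels == i] <- 0
  }
  mask
}

#' Keep contours with at least the mean area
#'
#' Drops every contour whose area is strictly below the mean area of the
#' input set; the largest contour always survives, so a non-empty input
#' gives a non-empty output.
#'
#' @param contours a contour tibble from [find_contours()].
#' @return the filtered contour tibble (same columns).
#' @export
filter_by_mean_area <- function(contours) {
  if (nrow(contours) == 0) return(contours)
  contours[contours$area_px >= mean(contours$area_px), , drop = FALSE]
}

#' Total contour area
#'
#' Sum of `area_px` over all contours in the set (outer and hole contours
#' alike). 0 for an empty set.
#'
#' @param contours a contour tibble from [find_contours()].
#' @return total area in px^2.
#' @export
total_area <- function(contours) {
  if (nrow(contours) == 0) return(0)
  sum(contours$area_px)
}
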