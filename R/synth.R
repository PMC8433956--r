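#' Specification of a synthetic wound photograph
#'
#' Describes a synthetic photograph used to validate the measurement
#' pipeline: a skin-tone background with per-pixel Gaussian sensor noise,
#' one or more dark reddish lesions (ellipses or smoothed random blobs),
#' optional small distractor specks and an optional linear illumination
#' ramp.  Defaults emulate the photographs the measurement method was
#' designed for: a 1024 x 706 px frame at 300 DPI, a lesion much darker
#' than the skin (luma contrast well above the 60 gray levels needed for
#' a clean Otsu split).
#'
#' @param width_px,height_px canvas size (default 1024 x 706).
#' @param dpi physical resolution embedded on write (default 300).
#' @param background_rgb skin-tone RGB triple (default c(205, 160, 140),
#'   luma about 171).
#' @param noise_sd per-channel Gaussian noise sigma (default 8).
#' @param lesions list of lesion specs; each is a list with `shape`
#'   (`"ellipse"` or `"blob"`), `center` `(x, y)` in 0-based pixels,
#'   `semi_axes` `(a, b)` (for a blob, `a` is the control radius), and
#'   optional `rgb` (default dark red c(120, 32, 28), luma about 58).
#' @param distractors number of small dark specks (radius 1--2 px, below
#'   any 50 px^2 contour-area cutoff) scattered away from the lesions.
#' @param illumination_gradient peak-to-peak luminance ramp across the
#'   image width, in gray levels (default 0 = off).
#' @param seed integer seed; generation is fully reproducible from it
#'   (Mersenne-Twister, inversion normals).
#' @return list of class `synth_wound_spec`.
#' @export
synth_wound_spec <- function(width_px = 1024, height_px = 706, dpi = 300,
                             background_rgb = c(205, 160, 140),
                             noise_sd = 8,
                             lesions = list(list(shape = "ellipse",
                                                 center = c(512, 353),
                                                 semi_axes = c(100, 60))),
                             distractors = 0,
                             illumination_gradient = 0,
                             seed = 1L) {
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px), dpi = dpi,
               background_rgb = background_rgb, noise_sd = noise_sd,
               lesions = lesions, distractors = as.integer(distractors),
               illumination_gradient = illumination_gradient,
               seed = as.integer(seed))
  class(spec) <- "synth_wound_spec"
  spec
}

luma <- function(rgb) sum(c(0.299, 0.587, 0.114) * rgb)

# 0/1 matrix of one rasterized lesion; pixel centres at 0-based integers
rasterize_lesion <- function(les, w, h) {
  a <- les$semi_axes[1]
  b <- if (length(les$semi_axes) > 1) les$semi_axes[2] else a
  cx <- les$center[1]; cy <- les$center[2]
  if (cx - a < 0 || cx + a > w - 1 || cy - b < 0 || cy + b > h - 1)
    abort_ws("lesion extends outside the canvas", "ws_spec_error")
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  if (identical(les$shape, "blob")) {
    # star-shaped blob: radius modulated by low-order harmonics
    amp <- les$amplitudes %||% c(0.12, 0.08, 0.05)
    phs <- les$phases %||% rep(0, length(amp))
    th <- atan2((y - cy) / b, (x - cx) / a)
    mod <- 1
    for (k in seq_along(amp))
      mod <- mod + amp[k] * cos((k + 1) * th + phs[k])
    ((x - cx) / a)^2 + ((y - cy) / b)^2 <= mod^2
  } else {
    ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic wound photograph with ground truth
#'
#' Rasterizes the lesions of a [synth_wound_spec()] onto the noisy
#' skin-tone background. The ground-truth mask is the exact rasterized
#' lesion set *before* noise; its pixel count, traced-contour shoelace
#' area, and cm^2 equivalent (pixel count scaled by
#' `(2.54 / dpi)^2`) are returned alongside.
#'
#' @param spec a [synth_wound_spec()].
#' @return list with `pixels` (`h x w x 3` array, 0--255), `meta`
#'   ([image_metadata()]), and `truth` (list: `mask` binary 0/255 matrix,
#'   `true_area_px` pixel count, `true_contour_area_px` summed shoelace
#'   area of the traced lesion boundaries, `true_area_cm2`).
#' @export
generate_wound <- function(spec) {
  w <- spec$width_px; h <- spec$height_px
  mask <- matrix(FALSE, h, w)
  les_mask <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    les_mask[[i]] <- rasterize_lesion(spec$lesions[[i]], w, h)
    mask <- mask | les_mask[[i]]
  }
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- spec$background_rgb[ch]
  for (i in seq_along(spec$lesions)) {
    col <- spec$lesions[[i]]$rgb %||% c(120, 32, 28)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[les_mask[[i]]] <- col[ch]
      img[, , ch] <- plane
    }
  }
  withr::with_seed(spec$seed, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", {
    if (spec$distractors > 0) {
      placed <- 0; tries <- 0
      while (placed < spec$distractors && tries < 1000) {
        tries <- tries + 1
        cx <- sample(10:(w - 11), 1); cy <- sample(10:(h - 11), 1)
        r <- sample(1:2, 1)
        xs <- (cx - r):(cx + r); ys <- (cy - r):(cy + r)
        sub <- mask[ys + 1, xs + 1]
        # keep specks clear of the lesions (and their close-by surroundings)
        box <- mask[max(1, cy - 39):min(h, cy + 41),
                    max(1, cx - 39):min(w, cx + 41)]
        if (any(box)) next
        for (x in xs) for (y in ys) {
          if ((x - cx)^2 + (y - cy)^2 <= r^2)
            img[y + 1, x + 1, ] <- c(70, 60, 55)
        }
        placed <- placed + 1
      }
    }
    if (spec$illumination_gradient != 0) {
      ramp <- matrix(rep(seq(-0.5, 0.5, length.out = w), each = h), h, w) *
        spec$illumination_gradient
      for (ch in 1:3) img[, , ch] <- img[, , ch] + ramp
    }
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                         dim = dim(img))
    }
  })
  img <- round_half_away(pmin(pmax(img, 0), 255))
  truth_mask <- matrix(ifelse(mask, 255, 0), h, w)
  tc <- find_contours(truth_mask)
  true_contour <- sum(tc$area_px[tc$type == "outer"])
  list(pixels = img,
       meta = image_metadata(w, h, spec$dpi, spec$dpi),
       truth = list(mask = truth_mask,
                    true_area_px = sum(mask),
                    true_contour_area_px = true_contour,
                    true_area_cm2 = sum(mask) * (2.54 / spec$dpi)^2))
}

#' Write a suite of synthetic fixtures with a JSON manifest
#'
#' Generates `n` synthetic photographs cycling through four scenarios --
#' a single clean lesion, two lesions, a lesion with distractor specks,
#' and a low-contrast lesion (luma contrast below 20 gray levels, flagged
#' `expected_failure` in the manifest as a documented hard case) -- and
#' writes them as PNG files carrying the DPI in their pHYs chunk, plus a
#' `manifest.json` describing each file and its ground truth.
#'
#' @param out_dir output directory (created if needed).
#' @param n number of fixtures (>= 1).
#' @param seed integer master seed; each fixture derives its own seed
#'   deterministically, so a rerun with the same arguments regenerates
#'   identical files.
#' @return the manifest as a tibble (one row per file), invisibly the
#'   same data is written to `manifest.json`.
#' @export
make_fixture_suite <- function(out_dir, n, seed = 1L) {
  if (n < 1) abort_ws("`n` must be >= 1", "ws_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    abort_ws(sprintf("cannot create '%s'", out_dir), "ws_io_error")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- fixture_spec(i, seed)
    g <- generate_wound(spec$spec)
    path <- file.path(out_dir, sprintf("fixture_%03d.png", i))
    write_wound_image(path, g$pixels, g$meta)
    rows[[i]] <- tibble::tibble(
      file = basename(path), scenario = spec$scenario,
      expected_failure = spec$expected_failure,
      seed = spec$spec$seed, dpi = spec$spec$dpi,
      true_area_px = g$truth$true_area_px,
      true_contour_area_px = g$truth$true_contour_area_px,
      true_area_cm2 = g$truth$true_area_cm2)
  }
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}

# deterministic per-fixture spec: scenario cycles, geometry from the seed
fixture_spec <- function(i, seed) {
  scen <- c("single", "multi", "distractor", "low_contrast")[(i - 1) %% 4 + 1]
  sub <- seed * 1000L + i                # derived seed, well below 2^31
  geom <- withr::with_seed(sub, {
    list(a = sample(40:130, 1), b = sample(40:100, 1),
         cx = sample(300:700, 1), cy = sample(250:450, 1),
         phs = stats::runif(3, 0, 2 * pi))
  })
  a <- geom$a; b <- min(geom$b, geom$a)   # keep b <= a
  base <- list(shape = "ellipse", center = c(geom$cx, geom$cy),
               semi_axes = c(a, b))
  lesions <- list(base)
  distract <- 0
  noise <- 8
  if (scen == "multi") {
    lesions <- list(
      list(shape = "ellipse", center = c(geom$cx - 180, geom$cy),
           semi_axes = c(min(a, 90), min(b, 70))),
      list(shape = "blob", center = c(geom$cx + 180, geom$cy),
           semi_axes = c(min(a, 80), min(b, 60)), phases = geom$phs))
  } else if (scen == "distractor") {
    distract <- 5
  }
  rgb <- if (scen == "low_contrast") c(190, 148, 128) else c(120, 32, 28)
  lesions <- lapply(lesions, function(l) { l$rgb <- rgb; l })
  list(scenario = scen, expected_failure = scen == "low_contrast",
       spec = synth_wound_spec(lesions = lesions, distractors = distract,
                               noise_sd = noise, seed = sub))
}
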