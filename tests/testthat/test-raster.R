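test_that("grayscale conversion applies the luma weights", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(as.vector(to_grayscale(px(255, 255, 255))), 255)
  expect_equal(as.vector(to_grayscale(px(0, 0, 0))), 0)
  # 0.299 * 255 = 76.245 rounds to 76
  expect_equal(as.vector(to_grayscale(px(255, 0, 0))), 76)
  expect_equal(as.vector(to_grayscale(px(0, 255, 0))), 150)
  expect_equal(as.vector(to_grayscale(px(0, 0, 255))), 29)
  # grayscale passes through unchanged
  m <- matrix(c(0, 100, 200, 255), 2, 2)
  expect_identical(to_grayscale(m), m)
  expect_error(to_grayscale(array(300, c(1, 1, 3))), class = "ws_invalid_image")
  expect_error(to_grayscale("not an image"), class = "ws_invalid_image")
})

test_that("box blur is a windowed mean with reflected borders", {
  const <- matrix(100, 8, 8)
  expect_equal(box_blur(const, 5), const)
  m <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
  expect_equal(box_blur(m, 1), m)
  z <- matrix(0, 5, 5); z[3, 3] <- 9
  b <- box_blur(z, 3)
  expect_equal(b[2:4, 2:4], matrix(1, 3, 3))
  expect_equal(sum(b), 9)
  expect_error(box_blur(m, 4), class = "ws_config_error")
  expect_error(box_blur(m, 7), class = "ws_config_error")  # k > min dim
})

test_that("box blur matches the brute-force sliding-window oracle", {
  withr::local_seed(11)
  for (k in c(3, 5)) {
    m <- matrix(sample(0:255, 12 * 9, replace = TRUE), 12, 9)
    expect_equal(box_blur(m, k), oracle_blur(m, k))
  }
})

test_that("box blur output range is within the input range", {
  withr::local_seed(12)
  for (i in 1:5) {
    m <- matrix(sample(40:200, 100, replace = TRUE), 10, 10)
    b <- box_blur(m, sample(c(3, 5, 7), 1))
    expect_gte(min(b), min(m))
    expect_lte(max(b), max(m))
  }
})

test_that("Otsu splits a bimodal image and matches the exhaustive oracle", {
  img <- matrix(c(rep(50, 32), rep(200, 32)), 8, 8)
  ot <- otsu_threshold(img)
  expect_gte(ot$threshold, 50)
  expect_lt(ot$threshold, 200)
  expect_identical(sort(unique(as.vector(ot$mask[img == 50]))), 0)
  expect_identical(sort(unique(as.vector(ot$mask[img == 200]))), 255)
  # single bright pixel
  img2 <- matrix(c(10, 10, 10, 240), 2, 2)
  expect_equal(sum(otsu_threshold(img2)$mask == 255), 1)
  expect_error(otsu_threshold(matrix(7, 4, 4)),
               class = "ws_degenerate_histogram")
})

test_that("Otsu equals the exhaustive 256-threshold argmax on random images", {
  withr::local_seed(21)
  for (i in 1:40) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_identical(otsu_threshold(img)$threshold, oracle_otsu(img))
  }
})

test_that("mask inversion is an involution that swaps the phases", {
  m <- matrix(c(0, 255, 255, 0), 2, 2)
  expect_equal(invert_mask(m), matrix(c(255, 0, 0, 255), 2, 2))
  expect_equal(invert_mask(matrix(0, 3, 3)), matrix(255, 3, 3))
  expect_equal(invert_mask(invert_mask(m)), m)
  expect_error(invert_mask(matrix(1, 2, 2)), class = "ws_invalid_mask")
})

test_that("elliptical structuring element follows the centre-in-ellipse rule", {
  se <- struct_element(11)
  expect_s3_class(se, "struct_element")
  expect_true(se$footprint[6, 6])          # origin always included
  expect_true(all(dim(se$footprint) == 11))
  # direct check of the discretization rule
  r <- 5
  for (di in -r:r) for (dj in -r:r)
    expect_identical(se$footprint[di + r + 1, dj + r + 1],
                     (di / r)^2 + (dj / r)^2 <= 1)
  expect_true(all(struct_element(1)$footprint))
  expect_true(all(struct_element(5, "rectangle")$footprint))
  expect_error(struct_element(10), class = "ws_config_error")
})

test_that("dilation and erosion match the set-definition oracle", {
  withr::local_seed(31)
  se <- struct_element(5)
  for (i in 1:5) {
    m <- random_margin_mask(20, 24, margin = 1, p = 0.3)
    expect_equal(mask_dilate(m, se), oracle_morph(m, se$footprint))
    expect_equal(mask_erode(m, se), oracle_morph(m, se$footprint, erode = TRUE))
  }
})

test_that("a single pixel dilates to the translated footprint", {
  m <- matrix(0, 31, 31); m[16, 16] <- 255
  se <- struct_element(11)
  d <- mask_dilate(m, se)
  expect_equal(d[11:21, 11:21] == 255, se$footprint)
  expect_equal(sum(d == 255), sum(se$footprint))
  expect_equal(mask_dilate(matrix(0, 15, 15), se), matrix(0, 15, 15))
  # two pixels 8 apart merge into one component under the 11x11 ellipse
  m2 <- matrix(0, 31, 31); m2[16, 12] <- 255; m2[16, 20] <- 255
  expect_equal(count_components(mask_dilate(m2, se)), 1)
})

test_that("erosion removes a border band and lone pixels", {
  m <- matrix(255, 20, 20)
  se <- struct_element(11)
  e <- mask_erode(m, se)
  expect_equal(e, oracle_morph(m, se$footprint, erode = TRUE))
  expect_true(all(e[1:5, ] == 0))    # footprint exits the image
  expect_true(all(e[6:15, 6:15] == 255))
  lone <- matrix(0, 15, 15); lone[8, 8] <- 255
  expect_equal(mask_erode(lone, se), matrix(0, 15, 15))
  expect_error(mask_dilate(matrix(0, 5, 5), se), class = "ws_config_error")
})

test_that("morphology invariants hold on random masks", {
  withr::local_seed(41)
  se <- struct_element(7)
  r <- 3
  for (i in 1:8) {
    m <- random_margin_mask(26, 30, margin = 2 * r + 1, p = 0.35)
    d <- mask_dilate(m, se)
    e <- mask_erode(m, se)
    expect_true(all(d >= m))                       # extensivity
    expect_true(all(e <= m))                       # anti-extensivity
    # duality away from the border (border padding is background on both
    # sides, so the identity holds exactly on the interior)
    dual <- invert_mask(mask_dilate(invert_mask(m), se))
    keep <- (r + 1):(nrow(m) - r)
    keepc <- (r + 1):(ncol(m) - r)
    expect_equal(e[keep, keepc], dual[keep, keepc])
    # closing: extensive and idempotent (foreground margin avoids clipping)
    cl <- mask_close(m, se)
    expect_true(all(cl >= m))
    expect_equal(mask_close(cl, se), cl)
  }
})

test_that("Canny finds a thin ring at the mask boundary", {
  expect_equal(canny_edges(matrix(0, 30, 30)), matrix(0, 30, 30))
  sq <- matrix(0, 64, 64); sq[23:42, 23:42] <- 255
  ed <- canny_edges(sq, 100, 200)
  expect_gt(sum(ed == 255), 0)
  # every edge pixel is within Chebyshev distance 1 of the true boundary
  bnd <- boundary_set(sq)
  near <- oracle_morph(matrix(ifelse(bnd, 255, 0), 64, 64),
                       matrix(TRUE, 3, 3))
  expect_true(all(near[ed == 255] == 255))
  # no edges deep inside or far outside
  expect_true(all(ed[30:35, 30:35] == 0))
  expect_true(all(ed[1:10, 1:10] == 0))
  expect_error(canny_edges(sq, 200, 100), class = "ws_config_error")
})

test_that("Canny on a filled disk gives a single closed ring", {
  h <- 64; w <- 64
  x <- matrix(rep(1:w, each = h), h, w); y <- matrix(rep(1:h, w), h, w)
  disk <- matrix(ifelse((x - 32)^2 + (y - 32)^2 <= 15^2, 255, 0), h, w)
  ed <- canny_edges(disk, 100, 200)
  expect_equal(count_components(ed), 1)
  # thin: no 3x3 block fully inside the edge set
  er <- mask_erode(ed, struct_element(3, "rectangle"))
  expect_equal(sum(er == 255), 0)
})

test_that("raster operators are deterministic", {
  withr::local_seed(51)
  m <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  expect_identical(box_blur(m, 5), box_blur(m, 5))
  expect_identical(otsu_threshold(m), otsu_threshold(m))
  mk <- otsu_threshold(m)$mask
  expect_identical(canny_edges(mk), canny_edges(mk))
})

test_that("morphology and blur agree with an independent implementation", {
  withr::local_seed(55)
  se <- struct_element(7)
  kern <- ifelse(se$footprint, 1, 0)
  for (i in 1:3) {
    m <- matrix(ifelse(stats::runif(30 * 26) < 0.35, 255, 0), 30, 26)
    expect_true(all(mask_dilate(m, se) / 255 == EBImage::dilate(m / 255, kern)))
    expect_true(all(mask_erode(m, se) / 255 == EBImage::erode(m / 255, kern)))
  }
  img <- matrix(sample(0:255, 40 * 30, replace = TRUE), 30, 40)
  ours <- box_blur(img, 5)
  ref <- EBImage::filter2(img, matrix(1 / 25, 5, 5), boundary = "replicate")
  # border policies differ (reflection vs replication); the interior of
  # the two results must agree to within rounding
  expect_lte(max(abs(ours[5:26, 5:36] - ref[5:26, 5:36])), 0.5)
})
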