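test_that("contours of simple masks: rectangle, hole, empty", {
  expect_equal(nrow(find_contours(matrix(0, 10, 10))), 0)
  sq <- matrix(0, 20, 20); sq[6:15, 6:15] <- 255
  cs <- find_contours(sq)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$type, "outer")
  # traced boundary of a filled 10x10 square has shoelace area (10-1)^2
  expect_equal(cs$area_px, 81)
  # close to but below the 100-pixel count, by about the half-perimeter
  expect_lt(cs$area_px, sum(sq == 255))
  # square with a hole: exactly two contours, outer first (raster order)
  sh <- sq; sh[9:12, 9:12] <- 0
  cs2 <- find_contours(sh)
  expect_equal(nrow(cs2), 2)
  expect_equal(cs2$type, c("outer", "hole"))
  expect_equal(cs2$area_px, c(81, 9))
})

test_that("shoelace area handles degenerate and known polygons", {
  expect_equal(contour_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  expect_equal(contour_area(rbind(c(0, 0), c(5, 5))), 0)
  expect_equal(contour_area(rbind(c(2, 2))), 0)
  # orientation does not matter
  expect_equal(contour_area(rbind(c(0, 0), c(0, 3), c(4, 0))), 6)
})

test_that("disjoint rectangles give one contour each and the (w-1)(h-1) total", {
  withr::local_seed(61)
  for (k in c(1, 3, 5)) {
    rr <- random_rectangles(k)
    cs <- find_contours(rr$mask)
    expect_equal(nrow(cs), k)
    expect_equal(sort(cs$area_px), sort(rr$areas))
    expect_equal(total_area(cs), sum(rr$areas))
  }
})

test_that("contours come out in raster-scan discovery order", {
  m <- matrix(0, 30, 30)
  m[20:25, 2:7] <- 255    # later in raster order
  m[3:8, 15:20] <- 255    # first row hit first
  cs <- find_contours(m)
  expect_equal(nrow(cs), 2)
  # first contour starts on the earlier raster row
  expect_lt(cs$points[[1]][1, 2], cs$points[[2]][1, 2])
})

test_that("remove_small_shapes applies a strict < cutoff", {
  m <- matrix(0, 40, 90)
  m[5:25, 3:23] <- 255                  # contour area 400
  m[30, 30] <- 255; m[30, 40] <- 255; m[30, 50] <- 255   # specks
  out <- remove_small_shapes(m, 50)
  expect_equal(nrow(find_contours(out)), 1)
  expect_equal(find_contours(out)$area_px, 400)
  expect_identical(remove_small_shapes(m, 0), m)
  # regions of contour areas {49.5 (approx), 50, 64}: strict < keeps >= 50
  m2 <- matrix(0, 60, 60)
  m2[3:10, 3:12] <- 255                 # 7 x 9 = 63 -> below? no: 63 >= 50
  # build exact areas: squares of side s have contour area (s-1)^2
  m3 <- matrix(0, 40, 120)
  m3[5:11, 5:11] <- 255                 # 6^2 = 36
  m3[5:13, 30:38] <- 255                # 8^2 = 64
  m3[5:12, 60:68] <- 255                # 7*8 = 56
  out3 <- remove_small_shapes(m3, 56)
  expect_equal(sort(find_contours(out3)$area_px), c(56, 64))
  # idempotent and anti-extensive
  expect_identical(remove_small_shapes(out3, 56), out3)
  expect_true(all(out3 <= m3))
})

test_that("mean-area filter keeps everything at or above the mean", {
  mk <- function(areas) tibble::tibble(
    contour = seq_along(areas), type = "outer",
    n_points = 4L, area_px = areas, points = vector("list", length(areas)))
  expect_equal(filter_by_mean_area(mk(100))$area_px, 100)
  expect_equal(filter_by_mean_area(mk(c(10, 10, 10)))$area_px, c(10, 10, 10))
  expect_equal(filter_by_mean_area(mk(c(5, 5, 110)))$area_px, 110)
  expect_equal(nrow(filter_by_mean_area(mk(numeric(0)))), 0)
  # the maximum always survives; output is a subset of the input
  withr::local_seed(71)
  for (i in 1:10) {
    a <- stats::runif(sample(1:8, 1), 1, 500)
    kept <- filter_by_mean_area(mk(a))
    expect_gte(nrow(kept), 1)
    expect_true(max(a) %in% kept$area_px)
    expect_true(all(kept$area_px %in% a))
  }
})

test_that("total_area sums the set and is 0 when empty", {
  empty <- find_contours(matrix(0, 5, 5))
  expect_equal(total_area(empty), 0)
  two <- tibble::tibble(contour = 1:2, type = "outer", n_points = 4L,
                        area_px = c(6, 4), points = vector("list", 2))
  expect_equal(total_area(two), 10)
})

test_that("hole areas participate in the filters", {
  sq <- matrix(0, 40, 40); sq[6:35, 6:35] <- 255; sq[16:25, 16:25] <- 0
  cs <- find_contours(sq)
  expect_equal(nrow(cs), 2)
  kept <- filter_by_mean_area(cs)
  # outer (841) survives, hole (81) is below the mean
  expect_equal(kept$type, "outer")
  expect_equal(total_area(cs), sum(cs$area_px))
})
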