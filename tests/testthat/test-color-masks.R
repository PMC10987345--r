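test_that("rgb_to_hsv matches the analytic hexcone conversion", {
  px <- function(r, g, b) rgb_image(array(c(r, g, b), dim = c(1, 1, 3)))
  red <- rgb_to_hsv(px(255, 0, 0))
  expect_equal(red$hue[1, 1], 0)
  expect_equal(red$sat[1, 1], 255)
  expect_equal(red$val[1, 1], 255)
  blue <- rgb_to_hsv(px(0, 0, 255))
  expect_equal(blue$hue[1, 1], 240)
  expect_equal(blue$sat[1, 1], 255)
  expect_equal(blue$val[1, 1], 255)
  # brown: H = 60*(g-b)/(max-min) = 60*40/90, S = 90/130*255, V = 130
  brown <- rgb_to_hsv(px(130, 80, 40))
  expect_equal(brown$hue[1, 1], 60 * 40 / 90, tolerance = 1e-12)
  expect_equal(brown$sat[1, 1], 90 / 130 * 255, tolerance = 1e-12)
  expect_equal(brown$val[1, 1], 130)
})

test_that("rgb_to_hsv reports hue in [0, 360) and rejects bad shapes", {
  set.seed(11)
  img <- rgb_image(array(sample(0:255, 32 * 32 * 3, TRUE), dim = c(32, 32, 3)))
  hsv <- rgb_to_hsv(img)
  expect_true(all(hsv$hue >= 0 & hsv$hue < 360))
  expect_true(all(hsv$sat >= 0 & hsv$sat <= 255))
  expect_true(all(hsv$val >= 0 & hsv$val <= 255))
  expect_error(rgb_to_hsv(array(0, dim = c(4, 4, 2))), "3")
})

test_that("extract_mask applies inclusive HSV windows conjunctively", {
  pr <- default_profiles()
  one <- function(h, s, v) hsv_image(matrix(h), matrix(s), matrix(v))
  expect_true(extract_mask(one(30, 100, 100), pr$ihc)[1, 1])
  expect_false(extract_mask(one(250, 100, 100), pr$ihc)[1, 1])
  expect_true(extract_mask(one(250, 100, 100), pr$nucleus)[1, 1])
  # inclusive bounds at the window edges
  expect_true(extract_mask(one(60, 60, 160), pr$ihc)[1, 1])
  expect_true(extract_mask(one(320, 60, 160), pr$ihc)[1, 1])
  expect_false(extract_mask(one(60.01, 100, 100), pr$ihc)[1, 1])
  # all-white image: V = 255 exceeds both value windows
  white <- hsv_image(matrix(0, 5, 5), matrix(0, 5, 5), matrix(255, 5, 5))
  expect_false(any(extract_mask(white, pr$ihc)))
  expect_false(any(extract_mask(white, pr$nucleus)))
})

test_that("masks are idempotent, monotone under widening, and rotation-equivariant", {
  set.seed(21)
  pr <- default_profiles()
  for (k in 1:5) {
    hsv <- random_hsv(24, 16)
    m1 <- extract_mask(hsv, pr$ihc)
    expect_identical(unclass(extract_mask(hsv, pr$ihc)), unclass(m1))
    wide <- channel_profile("ihc", list(c(0, 80), c(300, 360)), c(40, 255), c(0, 200))
    expect_true(all(unclass(extract_mask(hsv, wide))[unclass(m1)]))
    rot <- hsv_image(t(hsv$hue)[ncol(hsv$hue):1, ], t(hsv$sat)[ncol(hsv$sat):1, ],
                     t(hsv$val)[ncol(hsv$val):1, ])
    m_rot <- extract_mask(rot, pr$ihc)
    bare <- function(m) matrix(as.logical(m), nrow(m), ncol(m))
    expect_identical(bare(m_rot), t(bare(m1))[ncol(m1):1, ])
  }
})

test_that("count_positive_pixels restricts to polygons, boundary inclusive", {
  m <- matrix(TRUE, 10, 10)
  expect_identical(count_positive_pixels(matrix(FALSE, 3, 3)), 0L)
  expect_identical(count_positive_pixels(m), 100L)
  # axis-aligned 4x4 pixel square: vertices on the pixel centers 3..6
  sq <- rbind(c(3, 3), c(3, 6), c(6, 6), c(6, 3))
  expect_identical(count_positive_pixels(m, sq), 16L)
  # oracle: brute-force membership of every pixel center in the rectangle
  expect_identical(count_positive_pixels(m, sq),
                   sum(outer(1:10, 1:10, function(i, j) i >= 3 & i <= 6 & j >= 3 & j <= 6)))
  # sparse mask inside the region
  m2 <- matrix(FALSE, 10, 10); m2[4, 4] <- TRUE; m2[9, 9] <- TRUE
  expect_identical(count_positive_pixels(m2, sq), 1L)
  expect_error(count_positive_pixels(m, rbind(c(2, 2), c(2, 8), c(2, 5))), "area|region")
})

test_that("profiles round-trip through the YAML config format", {
  pr <- default_profiles()
  f <- tempfile(fileext = ".yaml")
  write_profiles(pr, f)
  back <- read_profiles(f)
  expect_equal(back$ihc$hue_windows, pr$ihc$hue_windows)
  expect_equal(back$ihc$sat_window, pr$ihc$sat_window)
  expect_equal(back$nucleus$val_window, pr$nucleus$val_window)
  unlink(f)
})
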