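test_that("otsu threshold separates a bimodal toy histogram", {
  x <- c(rep(30, 40), rep(200, 60))
  t <- otsu_threshold(x)
  expect_identical(t, oracle_otsu(x))
  expect_true(t >= 30 && t < 200)
  expect_identical(sum(x <= t), 40L)
  # symmetric two-level image: foreground = the dark half
  img <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  b <- otsu_binarize(img)
  expect_identical(unname(which(b)), unname(which(img == 0)))
})

test_that("otsu_binarize respects the mask and warns on degenerate histograms", {
  img <- matrix(100, 8, 8)
  img[1:4, ] <- 40
  mask <- matrix(FALSE, 8, 8); mask[3:6, ] <- TRUE
  b <- otsu_binarize(img, mask)
  expect_true(all(which(b) %in% which(mask)))     # restricted to mask
  expect_identical(sum(b), sum(mask & img == 40))  # dark side kept
  # constant inside the mask -> mask returned unchanged, with a warning
  const_mask <- matrix(FALSE, 8, 8); const_mask[1:2, ] <- TRUE
  expect_warning(b2 <- otsu_binarize(img, const_mask), "degenerate")
  expect_identical(matrix(as.logical(b2), 8, 8), const_mask)
  # empty foreground on an all-background selection
  expect_identical(sum(otsu_binarize(img, matrix(FALSE, 8, 8))), 0L)
})

test_that("denoise closes holes, keeps empties empty, and drops specks", {
  # disk with a punched 1-pixel hole -> solid again after closing
  m <- disk_mask(21, 21, 11, 11, 6)
  holed <- m; holed[11, 11] <- FALSE
  p <- denoise_params(dilation_radius = 0, closing_radius = 2, min_nucleus_area = 0)
  expect_true(denoise(holed, p)[11, 11])
  expect_identical(sum(denoise(matrix(FALSE, 9, 9), denoise_params())), 0L)
  # isolated pixel below the area floor is removed
  sp <- matrix(FALSE, 15, 15); sp[4, 4] <- TRUE
  p2 <- denoise_params(dilation_radius = 0, closing_radius = 0, min_nucleus_area = 5)
  expect_false(any(denoise(sp, p2)))
  expect_identical(oracle_n_components(sp), 1L)  # it was one 1-px component
})

test_that("distance_map equals O(n^2) brute force, border as background", {
  # all-foreground 5x5: distances to the border, centre largest
  ones <- matrix(TRUE, 5, 5)
  d <- distance_map(ones)
  expect_equal(d, oracle_distmap(ones))
  expect_identical(unname(which(d == max(d))), 13L)  # centre pixel
  expect_identical(distance_map(matrix(FALSE, 4, 6)), matrix(0, 4, 6))
  single <- matrix(FALSE, 7, 7); single[4, 4] <- TRUE
  expect_equal(distance_map(single)[4, 4], 1)
  set.seed(31)
  for (k in 1:5) {
    m <- matrix(runif(32 * 32) < 0.6, 32, 32)
    expect_equal(distance_map(m), oracle_distmap(m))
  }
})

test_that("count_apexes finds one apex per convex blob and splits dumbbells", {
  # two disjoint disks: apexes at the centres
  m <- disk_mask(60, 100, 30, 30, 8) | disk_mask(60, 100, 30, 70, 8)
  d <- distance_map(m)
  res <- count_apexes(d)
  expect_identical(res$count, 2L)
  expect_true(all(abs(res$apexes[, 1] - 30) <= 1))
  expect_equal(unname(sort(res$apexes[, 2])), c(30, 70), tolerance = 1)
  # the oracle scan agrees there are maxima only near the two centres
  om <- oracle_local_maxima(d)
  expect_true(all(pmin(abs(om[, 2] - 30), abs(om[, 2] - 70)) <= 2))
  # centroids: centre of gravity of each disk
  expect_equal(res$centroids[, 1], c(30, 30), tolerance = 0.1)
  # empty raster
  empty <- count_apexes(matrix(0, 10, 10))
  expect_identical(empty$count, 0L)
  expect_identical(nrow(empty$apexes), 0L)
  expect_identical(nrow(empty$centroids), 0L)
  # overlapping disks 12 px apart: still two apexes
  dumb <- disk_mask(40, 60, 20, 25, 8) | disk_mask(40, 60, 20, 37, 8)
  res2 <- count_apexes(distance_map(dumb))
  expect_identical(res2$count, 2L)
})

test_that("apexes lie on the mask and respect the separation floor", {
  set.seed(41)
  for (k in 1:4) {
    m <- matrix(FALSE, 80, 80)
    for (b in 1:6) m <- m | disk_mask(80, 80, runif(1, 12, 68), runif(1, 12, 68), runif(1, 4, 7))
    res <- count_apexes(distance_map(m))
    if (res$count) expect_true(all(m[res$apexes]))
    if (res$count > 1) {
      dd <- as.matrix(dist(res$apexes))
      expect_true(all(dd[upper.tri(dd)] >= res$params$min_apex_separation))
    }
  }
})

test_that("count equals component count for separated convex nuclei", {
  set.seed(51)
  for (k in 1:5) {
    m <- matrix(FALSE, 100, 100)
    placed <- matrix(numeric(0), 0, 2)
    while (nrow(placed) < 6) {
      c_new <- c(runif(1, 12, 88), runif(1, 12, 88))
      if (!nrow(placed) || all(sqrt(colSums((t(placed) - c_new)^2)) > 22))
        { m <- m | disk_mask(100, 100, c_new[1], c_new[2], 6); placed <- rbind(placed, c_new) }
    }
    res <- count_apexes(distance_map(m))
    expect_identical(res$count, oracle_n_components(m))
  }
})

test_that("count_nuclei recovers synthetic ground truth and is deterministic", {
  spec <- synthetic_spec(n_nuclei = 12, n_granules = 20, image_size = c(256, 256), seed = 5)
  scene <- generate_synthetic(spec)
  res <- suppressWarnings(count_nuclei(scene$image))
  expect_identical(res$count, scene$truth$nucleus_count)
  expect_identical(res$count, nrow(res$apexes))
  expect_identical(res$count, nrow(res$centroids))
  res2 <- suppressWarnings(count_nuclei(scene$image))
  expect_identical(res$apexes, res2$apexes)
  # blank image
  blank <- generate_synthetic(synthetic_spec(n_nuclei = 0, n_granules = 0,
                                             image_size = c(64, 64)))
  expect_identical(suppressWarnings(count_nuclei(blank$image))$count, 0L)
})

test_that("adding an isolated nucleus far from the rest increments the count", {
  scene <- generate_synthetic(synthetic_spec(n_nuclei = 6, n_granules = 0,
                                             image_size = c(300, 300), seed = 9))
  base <- suppressWarnings(count_nuclei(scene$image))
  px <- unclass(scene$image)
  # paint one more round nucleus in a spot known to be far from all others
  cy <- 280; cx <- 280
  d2 <- (scene$truth$nucleus_centers[, 1] - cy)^2 + (scene$truth$nucleus_centers[, 2] - cx)^2
  expect_gt(min(d2), 40^2)  # the corner really is free for this seed
  for (i in (cy - 7):(cy + 7)) for (j in (cx - 7):(cx + 7))
    if ((i - cy)^2 + (j - cx)^2 <= 49) px[i, j, ] <- c(60, 70, 150)
  more <- suppressWarnings(count_nuclei(rgb_image(px)))
  expect_identical(more$count, base$count + 1L)
})

test_that("the crowded-cell fallback triggers deterministically and is flagged", {
  # two small isolated nuclei plus one huge fused clump
  m <- disk_mask(120, 120, 15, 15, 6) | disk_mask(120, 120, 15, 105, 6)
  for (cx in seq(40, 90, by = 11)) m <- m | disk_mask(120, 120, 70, cx, 11)
  intensity <- matrix(200, 120, 120); intensity[m] <- 60
  res <- suppressWarnings(count_nuclei(intensity, nucleus_mask = m))
  expect_true(res$fallback_used)
  expect_true(res$count >= 4)
})
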