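write_labelme <- function(shapes, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(list(version = "5.0.1", shapes = shapes), path,
                       auto_unbox = TRUE, digits = NA)
  path
}

test_that("read_annotations parses the Labelme polygon dialect", {
  # one 'carcinoma' square: points are [x, y], 0-based
  f <- write_labelme(list(list(label = "carcinoma", shape_type = "polygon",
                               points = list(c(10, 20), c(50, 20), c(50, 60), c(10, 60)))))
  regs <- read_annotations(f)
  expect_length(regs, 1L)
  expect_identical(regs[[1]]$label, "carcinoma")
  expect_identical(nrow(regs[[1]]$polygon), 4L)
  # [x=10, y=20] -> (row=21, col=11) under the package's 1-based convention
  expect_equal(unname(regs[[1]]$polygon[1, ]), c(21, 11))
  expect_identical(regs[[1]]$source_file, f)

  # empty shape list
  f2 <- write_labelme(list())
  expect_length(read_annotations(f2), 0L)

  # triangle with shoelace area 50: base 10, height 10
  f3 <- write_labelme(list(list(label = "t", points = list(c(0, 0), c(10, 0), c(0, 10)))))
  tri <- read_annotations(f3)[[1]]
  expect_equal(region_area(tri), 50)
  sh <- tri$polygon
  n <- nrow(sh); j <- c(2:n, 1)  # independent shoelace evaluation
  expect_equal(abs(sum(sh[, 2] * sh[j, 1] - sh[j, 2] * sh[, 1])) / 2, 50)
})

test_that("read_annotations rejects malformed and self-intersecting input", {
  bad <- tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(read_annotations(bad), class = "mitoscore_parse_error")
  expect_error(read_annotations(tempfile()), class = "mitoscore_io_error")
  bow <- write_labelme(list(list(label = "bowtie",
                                 points = list(c(0, 0), c(10, 10), c(10, 0), c(0, 10)))))
  expect_error(read_annotations(bow), class = "mitoscore_validation_error")
  expect_error(read_annotations(bow), "bowtie")
  two <- write_labelme(list(list(label = "p", points = list(c(0, 0), c(5, 0)))))
  expect_error(read_annotations(two), "3 vertices")
})

test_that("annotations survive a write/read round trip", {
  poly <- rbind(c(3, 4), c(3, 40), c(30, 40), c(30, 4))
  f <- tempfile(fileext = ".json")
  write_annotations(list(list(label = "stroma", polygon = poly)), f)
  back <- read_annotations(f)
  expect_identical(back[[1]]$label, "stroma")
  expect_equal(unname(back[[1]]$polygon), unname(poly))
})

test_that("tile covers the image without overlap, truncating edge tiles", {
  g <- tile(c(4000, 4000), 2000)
  expect_identical(nrow(g$tiles), 4L)
  g2 <- tile(c(4100, 4000), 2000)
  expect_identical(nrow(g2$tiles), 6L)
  expect_identical(c(g2$nrow_tiles, g2$ncol_tiles), c(3L, 2L))
  bottom <- g2$tiles[g2$tiles$tile_row == 3, ]
  expect_true(all(bottom$r1 - bottom$r0 + 1L == 100L))
  g3 <- tile(c(100, 100), 2000)
  expect_identical(nrow(g3$tiles), 1L)
  expect_identical(c(g3$tiles$r1, g3$tiles$c1), c(100L, 100L))
  # partition: every pixel in exactly one tile
  cover <- matrix(0L, 41, 30)
  gt <- tile(c(41, 30), 16)
  for (i in seq_len(nrow(gt$tiles))) {
    t <- gt$tiles[i, ]
    cover[t$r0:t$r1, t$c0:t$c1] <- cover[t$r0:t$r1, t$c0:t$c1] + 1L
  }
  expect_true(all(cover == 1L))
  expect_error(tile(c(100, 100), 0), "tile_size")
})

test_that("per-tile IHC pixel counts sum to the whole-image count", {
  scene <- generate_synthetic(synthetic_spec(n_nuclei = 8, n_granules = 30,
                                             image_size = c(200, 220), seed = 23))
  ts <- score_tiles(scene$image, tile_size = 64)
  ihc <- extract_mask(rgb_to_hsv(scene$image), default_profiles()$ihc)
  expect_equal(sum(ts$scores$ihc_pixels), sum(ihc))
  expect_equal(sum(ts$scores$ihc_pixels), scene$truth$ihc_pixel_count)
  # nucleus counts may differ at tile borders, but only by the number of
  # border-straddling components
  res <- suppressWarnings(count_nuclei(scene$image))
  lab <- mitoscore:::label_components(res$mask)  # denoised mask, as counted
  cut_rows <- seq(64, 199, by = 64); cut_cols <- seq(64, 219, by = 64)
  straddle <- length(unique(c(
    lab[cut_rows, ][lab[cut_rows, ] > 0 & lab[cut_rows + 1L, ] > 0],
    lab[, cut_cols][lab[, cut_cols] > 0 & lab[, cut_cols + 1L] > 0])))
  expect_lte(abs(sum(ts$scores$nuclei) - scene$truth$nucleus_count), straddle)
})

test_that("heatmaps render deterministically and the grid CSV round-trips", {
  scene <- generate_synthetic(synthetic_spec(n_nuclei = 10, n_granules = 30,
                                             image_size = c(192, 192), seed = 29))
  ts <- score_tiles(scene$image, tile_size = 64)
  png1 <- tempfile(fileext = ".png"); csv1 <- tempfile(fileext = ".csv")
  out <- render_heatmap(ts, png1, csv1)
  expect_true(file.exists(png1) && file.exists(csv1))
  expect_equal(read_heatmap_grid(csv1), out$grid, ignore_attr = TRUE)
  expect_identical(dim(out$grid), c(3L, 3L))

  # uniform scores -> a uniform single-color cell area
  uni <- ts
  uni$scores$score <- rep(5, nrow(uni$scores))
  u <- render_heatmap(uni, tempfile(fileext = ".png"), tempfile(fileext = ".csv"),
                      cell_px = 8)
  img <- png::readPNG(u$png)
  cells <- img[1:24, 1:24, ]
  expect_identical(length(unique(as.vector(cells[, , 1]))), 1L)

  # a zero tile among positives sits at the scale minimum (palette[1])
  mix <- ts
  mix$scores$score <- c(0, rep(10, nrow(mix$scores) - 1))
  mx <- render_heatmap(mix, tempfile(fileext = ".png"), tempfile(fileext = ".csv"),
                       cell_px = 8)
  img2 <- png::readPNG(mx$png)
  low <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")[1]) / 255
  expect_equal(as.vector(img2[4, 4, ]), as.vector(low), tolerance = 0.005)
})
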