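#' Partition an image into square tiles
#'
#' Row-major, non-overlapping cover of the image by `tile_size` x
#' `tile_size` tiles; the last row/column of tiles is truncated at the
#' image edge. The default 2000 px matches one field of view at 40x.
#'
#' @param image an [rgb_image], a matrix, or a `c(height, width)` vector.
#' @param tile_size tile side length in pixels (`>= 1`).
#' @return A `tile_grid` object: list with `image_size`, `tile_size`,
#'   `nrow_tiles`, `ncol_tiles`, and a data.frame `tiles` with 1-based
#'   inclusive bounds `r0, r1, c0, c1`, tile indices `tile_row, tile_col`
#'   and a `tile_id`.
#' @examples
#' tile(c(4100, 4000), 2000)$tiles
#' @export
tile <- function(image, tile_size = 2000) {
  if (!is.numeric(tile_size) || length(tile_size) != 1L || tile_size < 1)
    stop_validation("'tile_size' must be >= 1")
  tile_size <- as.integer(tile_size)
  sz <- if (is.null(dim(image))) as.integer(image[1:2]) else dim(image)[1:2]
  if (any(sz < 1L)) stop_validation("image size must be >= 1 x 1")
  ntr <- as.integer(ceiling(sz[1] / tile_size))
  ntc <- as.integer(ceiling(sz[2] / tile_size))
  grid <- expand.grid(tile_col = seq_len(ntc), tile_row = seq_len(ntr))[, 2:1]
  r0 <- (grid$tile_row - 1L) * tile_size + 1L
  c0 <- (grid$tile_col - 1L) * tile_size + 1L
  tiles <- data.frame(
    tile_id = sprintf("tile_r%d_c%d", grid$tile_row, grid$tile_col),
    tile_row = grid$tile_row, tile_col = grid$tile_col,
    r0 = r0, r1 = pmin(r0 + tile_size - 1L, sz[1]),
    c0 = c0, c1 = pmin(c0 + tile_size - 1L, sz[2]),
    stringsAsFactors = FALSE)
  structure(list(image_size = sz, tile_size = tile_size,
                 nrow_tiles = ntr, ncol_tiles = ntc, tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d px in %d x %d tiles of %d px\n",
              x$image_size[1], x$image_size[2], x$nrow_tiles, x$ncol_tiles,
              x$tile_size))
  invisible(x)
}

#' Mito-score every tile of an image
#'
#' Stain masks are computed once on the full image (thresholding is
#' pixelwise, so per-tile masks are identical to cropped global masks);
#' nuclei are counted per tile on the cropped planes, so a nucleus is
#' counted in the tile holding its apex.
#'
#' @param image an [rgb_image].
#' @param tile_size tile side length in px.
#' @param profiles stain profiles.
#' @param params a [denoise_params] list.
#' @return A `mito_tile_scores` object: list with the `tile_grid` and a
#'   data.frame `scores` (one row per tile: counts, score, `fallback_used`).
#' @export
score_tiles <- function(image, tile_size = 2000, profiles = default_profiles(),
                        params = denoise_params()) {
  grid <- tile(image, tile_size)
  hsv <- rgb_to_hsv(image)
  ihc <- extract_mask(hsv, profiles$ihc)
  nuc <- extract_mask(hsv, profiles$nucleus)
  rows <- lapply(seq_len(nrow(grid$tiles)), function(i) {
    t <- grid$tiles[i, ]
    ri <- t$r0:t$r1; ci <- t$c0:t$c1
    cnt <- suppressWarnings(count_nuclei(hsv$val[ri, ci, drop = FALSE],
                                         nucleus_mask = nuc[ri, ci, drop = FALSE],
                                         params = params))
    s <- mito_score(sum(ihc[ri, ci]), cnt$count, region_label = t$tile_id,
                    fallback_used = cnt$fallback_used)
    as.data.frame(s)
  })
  scores <- cbind(grid$tiles, do.call(rbind, rows)[, -1])
  structure(list(grid = grid, scores = scores), class = "mito_tile_scores")
}

#' @export
print.mito_tile_scores <- function(x, ...) {
  print(x$grid)
  def <- x$scores$score[!is.nan(x$scores$score)]
  if (length(def))
    cat(sprintf("scores: n = %d defined, median %.4g, range %.4g - %.4g\n",
                length(def), median(def), min(def), max(def)))
  else cat("no tile has a defined score\n")
  invisible(x)
}

# Tile scores -> CSV with the package's file convention: 0-based half-open
# rectangles.
tile_scores_csv <- function(ts) {
  s <- ts$scores
  data.frame(region_label = s$tile_id,
             row0 = s$r0 - 1L, row1 = s$r1, col0 = s$c0 - 1L, col1 = s$c1,
             ihc_pixels = s$ihc_pixels, nuclei = s$nuclei,
             score = s$score, fallback_used = s$fallback_used,
             stringsAsFactors = FALSE)
}
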