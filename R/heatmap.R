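# Tiny 3x5 bitmap font (digits, sign, dot, e) so numeric labels can be
# burned into the heatmap raster without a graphics device.
.glyphs <- list(
  "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"), "7" = c("111","001","010","010","010"),
  "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"),
  "." = c("000","000","000","000","010"), "-" = c("000","000","111","000","000"),
  "+" = c("000","010","111","010","000"), "e" = c("000","111","101","110","111"),
  " " = c("000","000","000","000","000"))

bitmap_text <- function(s, scale = 2L) {
  chars <- strsplit(s, "")[[1]]
  glyph <- function(ch) {
    g <- .glyphs[[ch]]
    if (is.null(g)) g <- .glyphs[[" "]]
    m <- do.call(rbind, lapply(g, function(r) as.integer(strsplit(r, "")[[1]]) == 1L))
    cbind(m, FALSE)  # 1-px spacing
  }
  m <- do.call(cbind, lapply(chars, glyph))
  m[rep(seq_len(nrow(m)), each = scale), rep(seq_len(ncol(m)), each = scale)]
}

#' Render a per-tile Mito-score heatmap
#'
#' Draws one colored cell per tile on a viridis-like ramp, tiles with an
#' undefined score (no nuclei) in a reserved neutral grey, plus a vertical
#' color bar annotated with the numeric minimum and maximum. The numeric
#' grid is also written as CSV (`NA` marks undefined tiles), with one row
#' per tile row, so the CSV round-trips to the score matrix.
#'
#' @param scores a `mito_tile_scores` object from [score_tiles()].
#' @param out_png output PNG path.
#' @param out_csv output CSV path for the numeric grid; default: `out_png`
#'   with a `.csv` extension.
#' @param cell_px rendered size of one tile cell in px.
#' @param palette vector of colors for the low-to-high score ramp.
#' @param na_color color for undefined tiles.
#' @return Invisibly, a list with `png`, `csv` and the score `grid` matrix.
#' @export
render_heatmap <- function(scores, out_png, out_csv = NULL, cell_px = 24,
                           palette = grDevices::hcl.colors(256, "viridis"),
                           na_color = "grey70") {
  if (!inherits(scores, "mito_tile_scores"))
    stop_validation("'scores' must come from score_tiles()")
  if (is.null(out_csv)) out_csv <- sub("\\.png$", ".csv", out_png)
  g <- scores$grid
  grid <- matrix(NA_real_, g$nrow_tiles, g$ncol_tiles)
  grid[cbind(scores$scores$tile_row, scores$scores$tile_col)] <- scores$scores$score
  grid[is.nan(grid)] <- NA_real_

  def <- grid[!is.na(grid)]
  lo <- if (length(def)) min(def) else NA_real_
  hi <- if (length(def)) max(def) else NA_real_
  idx_of <- function(v) {
    if (!length(def) || hi == lo) rep(1L, length(v))
    else 1L + as.integer(round((length(palette) - 1L) * (v - lo) / (hi - lo)))
  }
  pal_rgb <- t(grDevices::col2rgb(palette)) / 255
  na_rgb <- as.vector(grDevices::col2rgb(na_color)) / 255

  ch <- g$nrow_tiles * cell_px
  cw <- g$ncol_tiles * cell_px
  bar_w <- 12L; gap <- 6L
  label_lo <- bitmap_text(format(signif(lo, 4)))
  label_hi <- bitmap_text(format(signif(hi, 4)))
  panel_w <- gap + bar_w + gap + max(ncol(label_lo), ncol(label_hi), 1L) + gap
  H <- max(ch, 2L * nrow(label_hi) + 20L)
  W <- cw + panel_w
  img <- array(1, dim = c(H, W, 3))

  for (tr in seq_len(g$nrow_tiles)) for (tc in seq_len(g$ncol_tiles)) {
    col <- if (is.na(grid[tr, tc])) na_rgb else pal_rgb[idx_of(grid[tr, tc]), ]
    rr <- ((tr - 1L) * cell_px + 1L):(tr * cell_px)
    cc <- ((tc - 1L) * cell_px + 1L):(tc * cell_px)
    for (k in 1:3) img[rr, cc, k] <- col[k]
  }

  # color bar: max at top, min at bottom
  if (length(def)) {
    bar_rows <- 1:H
    ramp <- idx_of(hi - (bar_rows - 1) / max(1, H - 1) * (hi - lo))
    for (k in 1:3) img[bar_rows, (cw + gap + 1L):(cw + gap + bar_w), k] <- pal_rgb[ramp, k]
    put_text <- function(label, top) {
      rr <- top:(top + nrow(label) - 1L)
      cc <- (cw + gap + bar_w + gap + 1L):(cw + gap + bar_w + gap + ncol(label))
      for (k in 1:3) {
        plane <- img[rr, cc, k]
        plane[label] <- 0
        img[rr, cc, k] <<- plane
      }
    }
    put_text(label_hi, 2L)
    put_text(label_lo, H - nrow(label_lo) - 1L)
  }

  atomic_write(out_png, function(p) png::writePNG(img, p))
  atomic_write(out_csv, function(p)
    write.csv(as.data.frame(grid), p, row.names = FALSE, quote = FALSE))
  invisible(list(png = out_png, csv = out_csv, grid = grid))
}

#' Read a heatmap grid CSV back into a score matrix
#'
#' @param path CSV written by [render_heatmap()].
#' @return Numeric matrix (`NA` = undefined tile).
#' @export
read_heatmap_grid <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("grid CSV not found: %s", path))
  unname(as.matrix(read.csv(path, colClasses = "numeric")))
}
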