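# Error condition helpers used across the package so the CLI can map failure
# classes to exit codes.
stop_io <- function(msg) stop(errorCondition(msg, class = c("mitoscore_io_error", "error")))
stop_parse <- function(msg) stop(errorCondition(msg, class = c("mitoscore_parse_error", "error")))
stop_validation <- function(msg) stop(errorCondition(msg, class = c("mitoscore_validation_error", "error")))

#' Construct an 8-bit RGB image
#'
#' @param pixels `height x width x 3` numeric array with values in 0-255.
#' @param pixel_size_um physical side length of one pixel in micrometres.
#'   The default 0.23 corresponds to a 40x whole-slide scan.
#' @return An object of class `rgb_image`: the integer pixel array with a
#'   `pixel_size_um` attribute.
#' @examples
#' img <- rgb_image(array(255L, dim = c(4, 4, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels, pixel_size_um = 0.23) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_validation("'pixels' must be a height x width x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_validation("channel values must lie in [0, 255]")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop_validation("'pixel_size_um' must be a single positive number")
  x <- array(as.integer(round(pixels)), dim = dim(pixels))
  structure(x, pixel_size_um = pixel_size_um, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, 8-bit RGB, %.3g um/px\n",
              d[1], d[2], attr(x, "pixel_size_um")))
  invisible(x)
}

#' Read an 8-bit RGB image from PNG or TIFF
#'
#' An alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams rgb_image
#' @return An [rgb_image].
#' @export
read_rgb_image <- function(path, pixel_size_um = 0.23) {
  if (!file.exists(path)) stop_io(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_io(sprintf("unsupported image format '.%s' (use PNG or TIFF): %s", ext, path))
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] != 3L) stop_validation(sprintf("expected 3 channels, got %d: %s", dim(px)[3], path))
  rgb_image(round(px * 255), pixel_size_um = pixel_size_um)
}

#' Write an RGB image or binary mask as PNG or TIFF
#'
#' Masks are written as single-channel images with foreground 255,
#' background 0.
#'
#' @param x an [rgb_image], a logical matrix (mask) or a numeric array.
#' @param path output path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x), nrow(x), ncol(x))
  else x <- unclass(x) / 255
  ext <- tolower(tools::file_ext(path))
  writer <- switch(ext,
    png = function(p) png::writePNG(x, p),
    tif = ,
    tiff = function(p) tiff::writeTIFF(x, p, bits.per.sample = 8L),
    stop_io(sprintf("unsupported output format '.%s': %s", ext, path))
  )
  atomic_write(path, writer)
  invisible(path)
}

# Write through a temp file in the same directory, then rename: failed runs
# leave no partial output.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", tools::file_ext(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop_io(sprintf("cannot write %s", path))
  invisible(path)
}

atomic_write_csv <- function(df, path) {
  atomic_write(path, function(p) write.csv(df, p, row.names = FALSE, quote = FALSE))
}
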