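#' Convert an RGB image to HSV planes
#'
#' Standard hexcone conversion. Hue is reported in degrees on `[0, 360)`;
#' saturation and value on the 8-bit scale `[0, 255]` (value equals the
#' maximum channel intensity). Achromatic pixels get hue 0 and saturation 0.
#'
#' @param image an [rgb_image] or a bare `h x w x 3` array in 0-255.
#' @return An object of class `hsv_image`: a list with numeric matrices
#'   `hue`, `sat`, `val`.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_hsv(rgb_image(px))$hue  # pure red -> 0 degrees
#' @export
rgb_to_hsv <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_validation("rgb_to_hsv() needs a height x width x 3 RGB array")
  d <- dim(image)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  h <- hsv[1, ] * 360
  h[h >= 360] <- 0
  out <- list(
    hue = matrix(h, d[1], d[2]),
    sat = matrix(hsv[2, ] * 255, d[1], d[2]),
    val = matrix(hsv[3, ] * 255, d[1], d[2])
  )
  structure(out, class = "hsv_image")
}

#' Assemble an HSV image from plane matrices
#'
#' @param hue matrix of hues in degrees `[0, 360)`.
#' @param sat,val matrices on `[0, 255]`, same shape as `hue`.
#' @return An `hsv_image`.
#' @export
hsv_image <- function(hue, sat, val) {
  if (!all(dim(hue) == dim(sat)) || !all(dim(hue) == dim(val)))
    stop_validation("hue, sat and val must share one shape")
  if (min(hue) < 0 || max(hue) >= 360) stop_validation("hue must lie in [0, 360)")
  if (min(sat) < 0 || max(sat) > 255 || min(val) < 0 || max(val) > 255)
    stop_validation("sat and val must lie in [0, 255]")
  structure(list(hue = hue, sat = sat, val = val), class = "hsv_image")
}

#' @export
print.hsv_image <- function(x, ...) {
  cat(sprintf("<hsv_image> %d x %d px (hue deg [0,360), S/V [0,255])\n",
              nrow(x$hue), ncol(x$hue)))
  invisible(x)
}
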