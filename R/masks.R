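as_binary_mask <- function(m, source_profile = NA_character_) {
  structure(m, source_profile = source_profile, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d positive, profile: %s\n",
              nrow(x), ncol(x), sum(x), attr(x, "source_profile")))
  invisible(x)
}

#' Extract a stain-class pixel mask from an HSV image
#'
#' A pixel is positive when its hue lies in any of the profile's hue
#' windows and its saturation and value lie in the saturation and value
#' windows. All bounds are inclusive; the three criteria are applied
#' conjunctively.
#'
#' @param hsv an `hsv_image` from [rgb_to_hsv()].
#' @param profile a [channel_profile].
#' @return A `binary_mask`: logical matrix of the image shape with a
#'   `source_profile` attribute.
#' @examples
#' img <- rgb_image(array(c(130, 80, 40), dim = c(1, 1, 3)))  # DAB brown
#' extract_mask(rgb_to_hsv(img), default_profiles()$ihc)[1, 1]
#' @export
extract_mask <- function(hsv, profile) {
  if (!inherits(hsv, "hsv_image")) stop_validation("'hsv' must be an hsv_image")
  if (!inherits(profile, "channel_profile")) stop_validation("'profile' must be a channel_profile")
  in_hue <- Reduce(`|`, lapply(profile$hue_windows, function(w)
    hsv$hue >= w[1] & hsv$hue <= w[2]))
  m <- in_hue &
    hsv$sat >= profile$sat_window[1] & hsv$sat <= profile$sat_window[2] &
    hsv$val >= profile$val_window[1] & hsv$val <= profile$val_window[2]
  as_binary_mask(m, source_profile = profile$name)
}

# Even-odd ray casting with inclusive boundary. `pr`, `pc` are pixel-center
# coordinates (1-based rows/cols); `poly` is an n x 2 (row, col) matrix.
points_in_polygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  y1 <- poly[, 1]; x1 <- poly[, 2]
  y2 <- poly[c(2:n, 1), 1]; x2 <- poly[c(2:n, 1), 2]
  inside <- logical(length(pr))
  onb <- logical(length(pr))
  for (e in seq_len(n)) {
    dy <- y2[e] - y1[e]; dx <- x2[e] - x1[e]
    L2 <- dy * dy + dx * dx
    if (L2 > 0) {
      tt <- ((pr - y1[e]) * dy + (pc - x1[e]) * dx) / L2
      cross <- (pr - y1[e]) * dx - (pc - x1[e]) * dy
      onb <- onb | (abs(cross) <= 1e-9 * sqrt(L2) & tt >= -1e-12 & tt <= 1 + 1e-12)
      crosses <- (y1[e] > pr) != (y2[e] > pr)
      xint <- x1[e] + (pr - y1[e]) / dy * dx
      inside <- xor(inside, crosses & (pc < xint))
    }
  }
  inside | onb
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(poly[, 2] * poly[j, 1] - poly[j, 2] * poly[, 1])) / 2
}

# Coerce polygon input (annotation_region or n x 2 matrix) to a matrix and
# validate it against image bounds.
as_polygon <- function(region, h = NULL, w = NULL) {
  if (inherits(region, "annotation_region")) region <- region$polygon
  region <- as.matrix(region)
  if (ncol(region) != 2L || nrow(region) < 3L)
    stop_validation("a region polygon needs >= 3 (row, col) vertices")
  if (polygon_area(region) <= 0)
    stop_validation("region polygon has zero area (empty region)")
  if (!is.null(h) && (min(region) < 0.5 - 1e-9 || max(region[, 1]) > h + 0.5 + 1e-9 ||
                      max(region[, 2]) > w + 0.5 + 1e-9))
    stop_validation("region polygon lies outside the image bounds")
  region
}

# Rasterize a polygon to a logical h x w matrix (pixel centers; boundary
# pixels count as inside).
polygon_mask <- function(poly, h, w) {
  m <- matrix(FALSE, h, w)
  r0 <- max(1L, floor(min(poly[, 1]))); r1 <- min(h, ceiling(max(poly[, 1])))
  c0 <- max(1L, floor(min(poly[, 2]))); c1 <- min(w, ceiling(max(poly[, 2])))
  if (r0 > r1 || c0 > c1) return(m)
  rows <- r0:r1; cols <- c0:c1
  grid <- expand.grid(r = rows, c = cols)
  m[cbind(grid$r, grid$c)] <- points_in_polygon(grid$r, grid$c, poly)
  m
}

#' Count positive pixels in a mask, optionally within a polygon region
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @param region optional polygon: an `annotation_region` or an `n x 2`
#'   matrix of `(row, col)` vertices (1-based pixel coordinates). Pixels on
#'   the polygon boundary count as inside.
#' @return Number of positive pixels (integer).
#' @export
count_positive_pixels <- function(mask, region = NULL) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop_validation("'mask' must be a logical matrix")
  if (is.null(region)) return(sum(mask))
  poly <- as_polygon(region, nrow(mask), ncol(mask))
  sum(mask & polygon_mask(poly, nrow(mask), ncol(mask)))
}
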