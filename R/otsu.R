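#' Otsu threshold of an 8-bit intensity sample
#'
#' Exhaustively equivalent threshold maximizing the between-class variance
#' of the 0-255 histogram (discriminant analysis), computed in closed form
#' from cumulative sums. The threshold `t` splits the sample into classes
#' `x <= t` and `x > t`; ties are broken toward the smallest `t`.
#'
#' @param x numeric vector of intensities in `[0, 255]` (rounded to
#'   integers internally).
#' @return The threshold, an integer in `0:254`.
#' @export
otsu_threshold <- function(x) {
  x <- as.integer(round(x))
  if (!length(x) || min(x) < 0L || max(x) > 255L)
    stop_validation("intensities must be a non-empty sample in [0, 255]")
  if (min(x) == max(x))
    stop_validation("degenerate histogram: a single intensity level")
  p <- tabulate(x + 1L, 256L) / length(x)
  i <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * i)
  muT <- mu[256]
  bcv <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  bcv <- bcv[1:255]          # t = 255 leaves the upper class empty
  which.max(bcv) - 1L
}

#' Binarize an intensity image by Otsu's method within a mask
#'
#' The histogram is built only from pixels where `mask` is `TRUE`, and the
#' returned foreground is restricted to that mask. With
#' `foreground = "low"` (default) the dark side of the threshold is kept,
#' matching hematoxylin nuclei, which are the darkest objects in a
#' brightfield field of view.
#'
#' If the masked intensities are constant the histogram is degenerate: the
#' mask is returned unchanged with a warning.
#'
#' @param intensity numeric matrix in `[0, 255]` (e.g. the HSV value plane).
#' @param mask optional logical matrix restricting the histogram and the
#'   result; default: the whole image.
#' @param foreground `"low"` to keep pixels `<=` threshold, `"high"` for
#'   the bright side.
#' @return A `binary_mask`.
#' @export
otsu_binarize <- function(intensity, mask = NULL, foreground = c("low", "high")) {
  foreground <- match.arg(foreground)
  if (!is.numeric(intensity) || is.null(dim(intensity)))
    stop_validation("'intensity' must be a numeric matrix")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  if (!all(dim(mask) == dim(intensity)))
    stop_validation("'mask' and 'intensity' shapes differ")
  if (!any(mask)) return(as_binary_mask(mask, "otsu"))
  vals <- intensity[mask]
  if (min(vals) == max(vals)) {
    warning("degenerate histogram inside mask (constant intensity); mask returned unchanged")
    return(as_binary_mask(unclass(mask), "otsu"))
  }
  t <- otsu_threshold(vals)
  keep <- if (foreground == "low") intensity <= t else intensity > t
  as_binary_mask(unclass(mask) & keep, "otsu")
}
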