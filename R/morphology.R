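# Thin wrappers around EBImage morphology. Masks are plain logical matrices
# here; EBImage wants numeric. All structuring elements are discs (odd-sized
# brushes), which are symmetric, so row/col orientation is immaterial.

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")

mt_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::imageData(EBImage::dilate(unclass(mask) * 1, disc_brush(radius))) > 0.5
}

mt_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::imageData(EBImage::erode(unclass(mask) * 1, disc_brush(radius))) > 0.5
}

mt_close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::imageData(EBImage::closing(unclass(mask) * 1, disc_brush(radius))) > 0.5
}

# 3x3 max filter (8-neighborhood), used for local-maximum detection.
max_filter3 <- function(x) {
  EBImage::imageData(EBImage::dilate(x, EBImage::makeBrush(3L, shape = "box")))
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged with a union-find pass over the label graph.
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(unclass(mask) * 1))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2])))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

component_areas <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(integer(0))
  tabulate(lab[lab > 0L], n)
}

component_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  cbind(row = as.numeric(tapply(idx[, 1], l, mean)),
        col = as.numeric(tapply(idx[, 2], l, mean)))
}

#' Euclidean distance map of a binary mask
#'
#' Each foreground pixel is assigned the exact Euclidean distance to the
#' nearest background pixel; background pixels hold 0. The image border
#' counts as background (a foreground pixel touching the edge is at
#' distance 1), so components touching the border cannot have unbounded
#' distances.
#'
#' @param mask logical matrix (or `binary_mask`).
#' @return Numeric matrix of the same shape, `>= 0` everywhere, 0 on
#'   background.
#' @export
distance_map <- function(mask) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop_validation("'mask' must be a logical matrix")
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  d <- EBImage::imageData(EBImage::distmap(pad, metric = "euclidean"))
  d[2:(h + 1L), 2:(w + 1L), drop = FALSE]
}
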