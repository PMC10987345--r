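# Independent brute-force oracles; these deliberately avoid the package's own
# code paths (and EBImage) wherever the computation under test is non-trivial.

# Per-pixel HSV window check with plain loops over the windows.
oracle_mask <- function(hsv, profile) {
  m <- matrix(FALSE, nrow(hsv$hue), ncol(hsv$hue))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    hh <- hsv$hue[i, j]
    in_h <- FALSE
    for (w in profile$hue_windows) if (hh >= w[1] && hh <= w[2]) in_h <- TRUE
    m[i, j] <- in_h &&
      hsv$sat[i, j] >= profile$sat_window[1] && hsv$sat[i, j] <= profile$sat_window[2] &&
      hsv$val[i, j] >= profile$val_window[1] && hsv$val[i, j] <= profile$val_window[2]
  }
  m
}

# Exhaustive search over all 255 split points maximizing between-class
# variance (first maximum wins).
oracle_otsu <- function(x) {
  x <- as.integer(round(x))
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# O(n^2) nearest-background Euclidean distance; the image border counts as
# background.
oracle_distmap <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  d <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) if (mask[i, j]) {
    db <- if (nrow(bg)) sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2)) else Inf
    d[i, j] <- min(db, i, j, h + 1 - i, w + 1 - j)
  }
  d
}

# All strict-neighborhood local maxima of a raster (8-neighborhood, >= all
# neighbours, > 0), without plateau handling.
oracle_local_maxima <- function(x) {
  h <- nrow(x); w <- ncol(x)
  out <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) if (x[i, j] > 0) {
    nb <- x[max(1, i - 1):min(h, i + 1), max(1, j - 1):min(w, j + 1)]
    if (x[i, j] >= max(nb)) out <- rbind(out, c(i, j))
  }
  out
}

# Recursive flood-fill component labeling, 8-connectivity.
oracle_n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  h <- nrow(mask); w <- ncol(mask)
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) if (mask[i0, j0] && lab[i0, j0] == 0L) {
    n <- n + 1L
    stack <- list(c(i0, j0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- p[1]; j <- p[2]
      if (i < 1 || j < 1 || i > h || j > w || !mask[i, j] || lab[i, j] != 0L) next
      lab[i, j] <- n
      for (di in -1:1) for (dj in -1:1) if (di || dj) stack[[length(stack) + 1L]] <- c(i + di, j + dj)
    }
  }
  n
}

# Random HSV image on the package's scales.
random_hsv <- function(h, w) {
  hsv_image(matrix(runif(h * w, 0, 359.99), h, w),
            matrix(runif(h * w, 0, 255), h, w),
            matrix(runif(h * w, 0, 255), h, w))
}

# Disk mask painted by hand.
disk_mask <- function(h, w, cy, cx, r) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  m
}
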