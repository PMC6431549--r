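# Internal grid helpers shared across modules. All grids are plain integer
# or double matrices in row-major (row, col) convention; NA marks nodata.

# Shift a matrix by (dr, dc), padding exposed cells with `fill`.
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Binary dilation with a (2r+1) x (2r+1) square structuring element,
# computed separably (row pass then column pass).
dilate_square <- function(m, r) {
  stopifnot(is.logical(m))
  if (r == 0L) return(m)
  rows <- m
  for (d in seq_len(r)) {
    rows <- rows | shift_mat(m, d, 0L, FALSE) | shift_mat(m, -d, 0L, FALSE)
  }
  out <- rows
  for (d in seq_len(r)) {
    out <- out | shift_mat(rows, 0L, d, FALSE) | shift_mat(rows, 0L, -d, FALSE)
  }
  out
}

# Count of TRUE 8-neighbours for every cell.
neighbor_count8 <- function(m) {
  stopifnot(is.logical(m))
  num <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      num <- num + shift_mat(m, dr, dc, FALSE)
    }
  }
  num
}

# Mean over a square moving window of radius r, edge windows clipped
# (separable sum / separable count).
box_mean <- function(m, r) {
  acc <- m
  cnt <- matrix(1, nrow(m), ncol(m))
  acc[is.na(acc)] <- 0
  cnt[is.na(m)] <- 0
  pass <- function(a, horizontal) {
    out <- a
    for (d in seq_len(r)) {
      if (horizontal) {
        out <- out + shift_mat(a, 0L, d, 0) + shift_mat(a, 0L, -d, 0)
      } else {
        out <- out + shift_mat(a, d, 0L, 0) + shift_mat(a, -d, 0L, 0)
      }
    }
    out
  }
  if (r > 0L) {
    acc <- pass(pass(acc, TRUE), FALSE)
    cnt <- pass(pass(cnt, TRUE), FALSE)
  }
  out <- acc / cnt
  out[is.na(m)] <- NA_real_
  out
}

# Exact Euclidean distance (in cells) to the nearest TRUE cell; +Inf when no
# cell is TRUE. Backed by EBImage's distance transform.
distance_to <- function(target) {
  stopifnot(is.logical(target))
  if (!any(target, na.rm = TRUE)) {
    return(matrix(Inf, nrow(target), ncol(target)))
  }
  bg <- matrix(1, nrow(target), ncol(target))
  bg[which(target)] <- 0
  d <- EBImage::distmap(bg, metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(d)), nrow(target), ncol(target))
}

# Gaussian-smoothed field (replicated boundary). The kernel is capped so
# its support fits the grid.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sigma <- min(sigma, (min(dim(m)) - 3) / 8)
  if (sigma <= 0) return(m)
  sm <- EBImage::gblur(m, sigma = sigma, boundary = "replicate")
  matrix(as.numeric(EBImage::imageData(sm)), nrow(m), ncol(m))
}

# Weighted sampling without replacement of `size` indices from `idx`.
sample_weighted <- function(idx, size, w) {
  pos <- w > 0 & !is.na(w)
  idx <- idx[pos]
  w <- w[pos]
  size <- min(size, length(idx))
  if (size == 0L) return(integer(0))
  if (length(idx) == 1L) return(rep(idx, size))
  sample(idx, size = size, replace = FALSE, prob = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
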