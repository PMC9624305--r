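# internal helpers shared across modules

# DFT sample frequencies in cycles per unit, numpy-style ordering
fft_freq <- function(n, d = 1) {
  c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * d)
}

# matrix of x (column) and y (row) centre coordinates for an n x m grid
grid_coords <- function(n, m, h, origin = c(0, 0)) {
  list(
    x = matrix(origin[1] + (seq_len(m) - 1) * h, n, m, byrow = TRUE),
    y = matrix(origin[2] + (seq_len(n) - 1) * h, n, m)
  )
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# bilinear interpolation of a gridded field at arbitrary physical points;
# clamps to the grid boundary (constant extrapolation)
bilinear_at <- function(values, h, origin, x, y) {
  n <- nrow(values); m <- ncol(values)
  cj <- (x - origin[1]) / h + 1
  ri <- (y - origin[2]) / h + 1
  cj <- pmin(pmax(cj, 1), m)
  ri <- pmin(pmax(ri, 1), n)
  j0 <- pmin(floor(cj), m - 1); i0 <- pmin(floor(ri), n - 1)
  fx <- cj - j0; fy <- ri - i0
  v00 <- values[cbind(i0, j0)]
  v01 <- values[cbind(i0, j0 + 1)]
  v10 <- values[cbind(i0 + 1, j0)]
  v11 <- values[cbind(i0 + 1, j0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}
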