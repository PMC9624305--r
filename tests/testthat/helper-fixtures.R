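# shared fixtures and small oracles

pa_substrate <- function() substrate_properties(470, 0.5)

# balanced two-patch Gaussian traction on an n x n grid (analytic, band
# limited for sigma >= 2h)
two_patch_traction <- function(n = 64, h = 1, peak = 50, sigma = 3) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE) * h
  y <- matrix(seq_len(n), n, n) * h
  g <- function(cx, cy) exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
  c1 <- 0.375 * n * h; c2 <- 0.625 * n * h; cm <- 0.5 * n * h
  tx <- peak * g(c1, cm) - peak * g(c2, cm)
  ty <- 0.6 * peak * g(cm, c1) - 0.6 * peak * g(cm, c2)
  traction_field(tx - mean(tx), ty - mean(ty), h)
}

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# 90-degree counter-clockwise rotation of a 2-component square field
rot90_mat <- function(m) t(m)[nrow(m):1, ]
rot90_field <- function(ax, ay) list(x = -rot90_mat(ay), y = rot90_mat(ax))

# noiseless Gaussian spot image with sub-pixel centre (x0, y0), 1-based px
gaussian_spot_image <- function(nx, ny, x0, y0, amp = 1000, sigma = 1.3,
                                background = 0) {
  jj <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ii <- matrix(seq_len(ny), ny, nx)
  background + amp * exp(-((jj - x0)^2 + (ii - y0)^2) / (2 * sigma^2))
}

sparse_df <- function(x, y, ux, uy) {
  out <- data.frame(x_um = x, y_um = y, ux_um = ux, uy_um = uy, quality = 1)
  class(out) <- c("sparse_displacements", "data.frame")
  out
}
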