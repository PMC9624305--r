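# Fourier-space elastic half-space solvers.
#
# Discrete convention: with grid spacing h, the continuous transform of a
# gridded field f is approximated by h^2 * DFT(f).  In the products
# u~ = G~ T~ and T~ = G~^{-1} u~ the h^2 factors cancel, so the solvers
# multiply raw DFT coefficients by the continuous G~(k) evaluated at the DFT
# wave vectors k = 2 pi * fft_freq(n, h).

pad_dims <- function(n, m, pad) {
  if (isTRUE(pad)) c(2L * n, 2L * m) else c(n, m)
}

fttc_greens_grids <- function(nn, mm, h, substrate) {
  kx <- 2 * pi * fft_freq(mm, h)
  ky <- 2 * pi * fft_freq(nn, h)
  kxg <- matrix(kx, nn, mm, byrow = TRUE)
  kyg <- matrix(ky, nn, mm)
  kxg[1, 1] <- 1  # placeholder; the k = 0 mode is overwritten by convention
  g <- greens_tensor_hat(kxg, kyg, substrate)
  g$gxx[1, 1] <- 0; g$gxy[1, 1] <- 0; g$gyy[1, 1] <- 0
  g
}

#' Forward elastic problem: displacement generated by a traction field
#'
#' Solves the Boussinesq convolution `u = G * T` for a traction field on a
#' uniform grid by multiplication with the half-space Green's tensor in
#' Fourier space.  Because a cell exerts a balanced force system, the mean
#' traction is projected to zero before transforming (the k = 0 mode of the
#' Green's tensor is singular and carries no tangential information); callers
#' passing an unbalanced field accept that projection.
#'
#' The physical convolution is aperiodic, so by default the traction is
#' zero-padded to twice the linear grid size before the FFT and the result
#' cropped back, which suppresses wrap-around from the periodic images.
#' `pad = FALSE` selects the purely periodic discrete operator; use it when
#' an exactly invertible discrete pair with [fttc_invert()] is needed.
#'
#' @param traction A [traction_field()] (finite values, uniform grid).
#' @param substrate A [substrate_properties()] object.
#' @param pad Zero-pad to 2x linear size before transforming (default TRUE).
#'
#' @return A [displacement_field()] on the same grid (um).
#' @examples
#' tr <- make_traction_pattern(n_sites = 4, seed = 1)
#' u <- forward_displacement(tr, substrate_properties(470))
#' @export
forward_displacement <- function(traction, substrate, pad = TRUE) {
  stopifnot(inherits(traction, "traction_field"))
  substrate <- as_substrate(substrate)
  tx <- traction$tx - mean(traction$tx)
  ty <- traction$ty - mean(traction$ty)
  h <- traction$grid_spacing
  n <- nrow(tx); m <- ncol(tx)
  d <- pad_dims(n, m, pad)
  txp <- matrix(0, d[1], d[2]); typ <- matrix(0, d[1], d[2])
  txp[1:n, 1:m] <- tx; typ[1:n, 1:m] <- ty
  g <- fttc_greens_grids(d[1], d[2], h, substrate)
  txh <- stats::fft(txp); tyh <- stats::fft(typ)
  uxh <- g$gxx * txh + g$gxy * tyh
  uyh <- g$gxy * txh + g$gyy * tyh
  np <- prod(d)
  ux <- Re(stats::fft(uxh, inverse = TRUE)) / np
  uy <- Re(stats::fft(uyh, inverse = TRUE)) / np
  displacement_field(ux[1:n, 1:m], uy[1:n, 1:m], h, traction$origin)
}

#' Inverse elastic problem: Fourier transform traction cytometry
#'
#' Recovers the traction stress field from a measured substrate displacement
#' field by inverting the Boussinesq relation per wave vector,
#' `T~ = G~^{-1} u~`.  With `regularization = 0` the inversion is exact in
#' Fourier space; with `lambda > 0` each wave vector gets the zeroth-order
#' Tikhonov solution minimizing `||G~ T~ - u~||^2 + lambda ||T~||^2`, which
#' damps the noise-amplifying high-frequency modes of the ill-posed inverse
#' problem.  The zero-frequency traction is set to zero (zero net force
#' convention).  `lambda` has units of `(um/Pa)^2`, the square of the
#' Green's tensor entries.
#'
#' The displacement window is zero-padded to 2x linear size by default to
#' keep the deconvolution aperiodic, matching [forward_displacement()];
#' `pad = FALSE` gives the exact discrete inverse of the unpadded forward
#' operator.
#'
#' @param displacement A [displacement_field()]; any gaps must already be
#'   interpolated (`validity_mask` all TRUE).
#' @param substrate A [substrate_properties()] object.
#' @param regularization Non-negative Tikhonov parameter `lambda`.
#' @param pad Zero-pad to 2x linear size (default TRUE).
#'
#' @return A [traction_field()] on the same grid, with
#'   `regularization_used` recorded.
#' @export
fttc_invert <- function(displacement, substrate, regularization = 0,
                        pad = TRUE) {
  stopifnot(inherits(displacement, "displacement_field"))
  substrate <- as_substrate(substrate)
  stopifnot_scalar(regularization, "regularization", nonneg = TRUE)
  if (!all(displacement$validity_mask)) {
    stop("displacement field has unfilled gaps; interpolate before inversion",
         call. = FALSE)
  }
  ux <- displacement$ux; uy <- displacement$uy
  n <- nrow(ux); m <- ncol(ux)
  if (n < 4 || m < 4) {
    stop("displacement grid must be at least 4 x 4", call. = FALSE)
  }
  h <- displacement$grid_spacing
  d <- pad_dims(n, m, pad)
  uxp <- matrix(0, d[1], d[2]); uyp <- matrix(0, d[1], d[2])
  uxp[1:n, 1:m] <- ux; uyp[1:n, 1:m] <- uy
  g <- fttc_greens_grids(d[1], d[2], h, substrate)
  uxh <- stats::fft(uxp); uyh <- stats::fft(uyp)
  # per-wave-vector Tikhonov normal equations; G~ is symmetric so G^T = G
  a <- g$gxx; b <- g$gxy; dd <- g$gyy
  mxx <- a * a + b * b + regularization
  mxy <- b * (a + dd)
  myy <- dd * dd + b * b + regularization
  det <- mxx * myy - mxy^2
  det[1, 1] <- 1  # k = 0 solved by convention below
  rx <- a * uxh + b * uyh
  ry <- b * uxh + dd * uyh
  txh <- (myy * rx - mxy * ry) / det
  tyh <- (-mxy * rx + mxx * ry) / det
  txh[1, 1] <- 0; tyh[1, 1] <- 0
  np <- prod(d)
  tx <- Re(stats::fft(txh, inverse = TRUE)) / np
  ty <- Re(stats::fft(tyh, inverse = TRUE)) / np
  traction_field(tx[1:n, 1:m], ty[1:n, 1:m], h, displacement$origin,
                 regularization_used = regularization)
}
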