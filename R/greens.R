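#' Boussinesq surface Green's function in Fourier space
#'
#' Evaluates the 2x2 tensor `G~(k)` relating the Fourier transforms of the
#' tangential surface traction and the in-plane surface displacement of a
#' semi-infinite elastic half-space, `u~(k) = G~(k) T~(k)`:
#'
#' \deqn{\tilde G_{ij}(k) = \frac{2(1+\sigma)}{E k^3}
#'       \left(k^2 \delta_{ij} - \sigma k_i k_j\right)}
#'
#' i.e. diagonal terms `(1-s) k^2 + s ky^2` (xx) and `(1-s) k^2 + s kx^2`
#' (yy) and off-diagonal `-s kx ky`, all times `2(1+s)/(E k^3)`, with `s` the
#' Poisson ratio and `E` the Young's modulus of the substrate.  Written as a
#' prefactor `A/(2 pi k^3)` times the bracketed tensor this corresponds to
#' `A = 4 pi (1+s)/E`; the value is pinned by matching the real-space
#' Boussinesq point-force solution ([boussinesq_point_displacement()]) under
#' the package's FFT normalization, and that match is asserted in the test
#' suite.  The sign of the off-diagonal term is the one produced by Fourier
#' transforming the real-space kernel, whose off-diagonal part is
#' `+ s x y / r^3`.
#'
#' Units: with `k` in rad/um and `E` in Pa, `G~` is in um/Pa (the continuous
#' transform of a kernel in um / (Pa um^2)).
#'
#' @param kx,ky Wave-vector components in rad/um.  Vectorized; `(0, 0)` is a
#'   domain error (the k = 0 mode carries no tangential elastic information
#'   and is handled by the zero-net-traction convention in the solvers).
#' @param substrate A [substrate_properties()] object.
#'
#' @return A list with components `gxx`, `gxy`, `gyy` shaped like `kx`.
#' @seealso [forward_displacement()], [fttc_invert()]
#' @export
greens_tensor_hat <- function(kx, ky, substrate) {
  substrate <- as_substrate(substrate)
  if (any(kx == 0 & ky == 0)) {
    stop("greens_tensor_hat is singular at the zero wave vector", call. = FALSE)
  }
  s <- substrate$poisson_ratio
  k2 <- kx^2 + ky^2
  pref <- 2 * (1 + s) / (substrate$young_modulus * k2 * sqrt(k2))
  list(
    gxx = pref * (k2 - s * kx^2),
    gxy = pref * (-s * kx * ky),
    gyy = pref * (k2 - s * ky^2)
  )
}

#' Boussinesq surface Green's function in real space
#'
#' The classical closed-form surface displacement of an elastic half-space
#' under a tangential point force applied at the origin of its surface:
#'
#' \deqn{G_{ij}(r) = \frac{1+\sigma}{\pi E}
#'       \left[(1-\sigma)\frac{\delta_{ij}}{r} +
#'             \sigma \frac{x_i x_j}{r^3}\right]}
#'
#' so that `u_i(r) = G_ij(r) F_j` for a point force `F` (in Pa um^2 = pN
#' when assembled from a traction times a cell area).  This is the
#' real-space counterpart of [greens_tensor_hat()] and serves as the
#' independent reference for calibrating and validating the Fourier
#' pipeline.
#'
#' @param x,y Observation offsets from the force application point, um.
#' @param fx,fy Point force components in Pa um^2.
#' @param substrate A [substrate_properties()] object.
#'
#' @return A list with displacement components `ux`, `uy` (um), shaped
#'   like `x`.
#' @export
boussinesq_point_displacement <- function(x, y, fx, fy, substrate) {
  substrate <- as_substrate(substrate)
  s <- substrate$poisson_ratio
  r2 <- x^2 + y^2
  r <- sqrt(r2)
  c0 <- (1 + s) / (pi * substrate$young_modulus)
  gxx <- c0 * ((1 - s) / r + s * x^2 / (r * r2))
  gyy <- c0 * ((1 - s) / r + s * y^2 / (r * r2))
  gxy <- c0 * (s * x * y / (r * r2))
  list(ux = gxx * fx + gxy * fy, uy = gxy * fx + gyy * fy)
}

#' Real-space Boussinesq convolution (direct summation)
#'
#' Computes the surface displacement generated by a gridded traction field
#' by brute-force summation of the real-space Green's function over all
#' loaded grid cells, treating each cell as a patch of uniform traction.
#' The singular and near-singular kernel cells (within `refine_radius` grid
#' spacings of a source) are integrated by midpoint quadrature on a
#' `subsamples x subsamples` sub-grid; the 1/r singularity is integrable, and
#' even-order midpoint nodes never hit r = 0.
#'
#' This direct route is O(N^2 P) in the number of grid nodes N^2 and loaded
#' cells P and exists as the slow, convention-free reference implementation
#' against which the Fourier solver ([forward_displacement()]) is validated.
#' It makes no periodicity assumption.
#'
#' @param traction A [traction_field()].
#' @param substrate A [substrate_properties()] object.
#' @param refine_radius Radius (in grid spacings) below which kernel cells
#'   are sub-integrated rather than point-sampled.
#' @param subsamples Midpoint sub-grid order for the refined cells.
#'
#' @return A [displacement_field()] on the same grid.
#' @export
boussinesq_displacement <- function(traction, substrate,
                                    refine_radius = 2.5, subsamples = 12) {
  stopifnot(inherits(traction, "traction_field"))
  substrate <- as_substrate(substrate)
  tx <- traction$tx; ty <- traction$ty
  h <- traction$grid_spacing
  n <- nrow(tx); m <- ncol(tx)
  ux <- matrix(0, n, m); uy <- matrix(0, n, m)
  nz <- which(tx != 0 | ty != 0, arr.ind = TRUE)
  off <- ((seq_len(subsamples) - 0.5) / subsamples - 0.5) * h
  ox <- matrix(off, subsamples, subsamples, byrow = TRUE)
  oy <- matrix(off, subsamples, subsamples)
  s <- substrate$poisson_ratio
  c0 <- (1 + s) / (pi * substrate$young_modulus)
  gfun <- function(x, y) {
    r2 <- x^2 + y^2
    r <- sqrt(r2)
    list(gxx = c0 * ((1 - s) / r + s * x^2 / (r * r2)),
         gxy = c0 * (s * x * y / (r * r2)),
         gyy = c0 * ((1 - s) / r + s * y^2 / (r * r2)))
  }
  for (q in seq_len(nrow(nz))) {
    i <- nz[q, 1]; j <- nz[q, 2]
    fx <- tx[i, j] * h^2; fy <- ty[i, j] * h^2
    xd <- outer(rep(1, n), (seq_len(m) - j) * h)
    yd <- outer((seq_len(n) - i) * h, rep(1, m))
    g <- gfun(xd, yd)
    near <- which(xd^2 + yd^2 < (refine_radius * h)^2, arr.ind = TRUE)
    for (p in seq_len(nrow(near))) {
      a <- near[p, 1]; b <- near[p, 2]
      gs <- gfun((b - j) * h + ox, (a - i) * h + oy)
      g$gxx[a, b] <- mean(gs$gxx)
      g$gxy[a, b] <- mean(gs$gxy)
      g$gyy[a, b] <- mean(gs$gyy)
    }
    ux <- ux + g$gxx * fx + g$gxy * fy
    uy <- uy + g$gxy * fx + g$gyy * fy
  }
  displacement_field(ux, uy, h, traction$origin)
}
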