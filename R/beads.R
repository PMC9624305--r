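# Bead image processing: detection, linking, gridding.

#' Detect fluorescent beads with sub-pixel precision
#'
#' Finds diffraction-limited spots as local intensity maxima above a noise
#' floor, suppresses detections closer than `min_separation`, and refines
#' each to sub-pixel precision with an iterative Gaussian-weighted centroid:
#' the centroid of background-subtracted intensity in a 7x7 px window, with
#' Gaussian weights re-centred on the running estimate until convergence.
#' For a Gaussian spot this estimator has no truncation bias (the
#' weight-intensity product concentrates the effective window on the spot),
#' unlike a plain hard-window centroid.
#'
#' @param image Numeric matrix of non-negative intensities (row = y,
#'   column = x), at least 16 x 16 px.
#' @param pixel_size Pixel size in um/px.
#' @param min_separation Minimum allowed distance between detections, um.
#' @param intensity_threshold Detection threshold as a fraction of the
#'   background-subtracted image maximum; combined with a 5-sigma noise
#'   floor estimated from the median absolute deviation.
#' @param psf_sigma Gaussian width of the imaged spots in um; sets the
#'   centroid weighting scale.  Default 1.3 px.
#'
#' @return A data.frame with columns `x_um`, `y_um` (sub-pixel positions,
#'   pixel-centre convention with the first pixel centre at 0) and
#'   `intensity` (peak value above background).  A flat or empty image
#'   yields zero rows.
#' @export
detect_beads <- function(image, pixel_size = 1, min_separation = 4 * pixel_size,
                         intensity_threshold = 0.2,
                         psf_sigma = 1.3 * pixel_size) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 16 || ncol(image) < 16) {
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  }
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(min_separation, "min_separation", positive = TRUE)
  ny <- nrow(image); nx <- ncol(image)
  bg <- stats::median(image)
  noise <- stats::mad(image)
  rng <- max(image) - bg
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0))
  if (rng <= 0) return(empty)
  thr <- bg + max(5 * noise, intensity_threshold * rng)

  # 8-neighbour local maxima via shifted comparisons
  padm <- matrix(-Inf, ny + 2, nx + 2)
  padm[2:(ny + 1), 2:(nx + 1)] <- image
  shifts <- list(c(0, 1), c(2, 1), c(1, 0), c(1, 2),
                 c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  ismax <- matrix(TRUE, ny, nx)
  for (s in shifts) {
    ismax <- ismax & image >= padm[s[1] + 1:ny, s[2] + 1:nx]
  }
  cand <- which(ismax & image > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  # greedy brightest-first suppression within min_separation
  sep_px <- min_separation / pixel_size
  ord <- order(image[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (q in seq_len(nrow(cand))) {
    if (!keep[q] || q == nrow(cand)) next
    rest <- (q + 1):nrow(cand)
    d2 <- (cand[rest, 1] - cand[q, 1])^2 + (cand[rest, 2] - cand[q, 2])^2
    keep[rest][d2 < sep_px^2] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]

  sig_px <- psf_sigma / pixel_size
  pos <- matrix(NA_real_, nrow(cand), 3)
  for (q in seq_len(nrow(cand))) {
    ctr <- refine_centroid(image, cand[q, 1], cand[q, 2], bg, sig_px)
    if (!is.null(ctr)) pos[q, ] <- c(ctr, image[cand[q, 1], cand[q, 2]] - bg)
  }
  pos <- pos[stats::complete.cases(pos), , drop = FALSE]
  data.frame(
    x_um = (pos[, 1] - 1) * pixel_size,
    y_um = (pos[, 2] - 1) * pixel_size,
    intensity = pos[, 3]
  )
}

# iterative Gaussian-weighted centroid; returns c(x_px, y_px) 1-based or NULL
refine_centroid <- function(image, i, j, bg, sig_px, win = 3L, iters = 8L) {
  ny <- nrow(image); nx <- ncol(image)
  if (i <= win || i > ny - win || j <= win || j > nx - win) return(NULL)
  ii <- (i - win):(i + win); jj <- (j - win):(j + win)
  v <- image[ii, jj] - bg
  v[v < 0] <- 0
  jg <- outer(rep(1, length(ii)), jj)
  ig <- outer(ii, rep(1, length(jj)))
  cx <- j; cy <- i
  for (t in seq_len(iters)) {
    w <- exp(-((jg - cx)^2 + (ig - cy)^2) / (2 * sig_px^2))
    s <- sum(w * v)
    if (s <= 0) return(NULL)
    cx <- sum(w * v * jg) / s
    cy <- sum(w * v * ig) / s
  }
  c(cx, cy)
}

#' Link beads between the reference and loaded images
#'
#' Matches each reference bead to its mutual nearest neighbour among the
#' loaded-image beads, keeping only pairs closer than `max_displacement`;
#' beads without a mutual partner inside the search radius are dropped.  The
#' per-bead displacement vector is the loaded-minus-reference position
#' difference.  Mutual-nearest-neighbour linking is reliable when the true
#' displacements are smaller than the typical bead spacing, the regime in
#' which the tracking default (`max_displacement` of half the mean spacing)
#' operates.
#'
#' @param ref_positions,loaded_positions Data frames with columns `x_um`,
#'   `y_um` (e.g. from [detect_beads()]), or 2-column matrices, non-empty.
#' @param max_displacement Search radius in um (> 0).  Default: 0.75 times
#'   the mean nearest-neighbour spacing of the reference beads -- large
#'   enough for the bead excursions a soft gel produces, small enough to
#'   keep mutual-nearest-neighbour links unambiguous.
#'
#' @return A `sparse_displacements` data.frame with columns `x_um`, `y_um`
#'   (reference positions), `ux_um`, `uy_um` (displacement vectors) and
#'   `quality` (1 minus the matched-distance fraction of the search radius).
#' @export
match_beads <- function(ref_positions, loaded_positions,
                        max_displacement = NULL) {
  a <- as_xy(ref_positions); b <- as_xy(loaded_positions)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("both position lists must be non-empty", call. = FALSE)
  }
  if (is.null(max_displacement)) {
    max_displacement <- 0.75 * mean_nn_spacing(a)
  }
  stopifnot_scalar(max_displacement, "max_displacement", positive = TRUE)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  ia <- max.col(-d2, ties.method = "first")            # nearest b for each a
  ib <- max.col(-t(d2), ties.method = "first")         # nearest a for each b
  da <- d2[cbind(seq_len(nrow(a)), ia)]
  mutual <- which(ib[ia] == seq_len(nrow(a)) & da <= max_displacement^2)
  out <- data.frame(
    x_um = a[mutual, 1],
    y_um = a[mutual, 2],
    ux_um = b[ia[mutual], 1] - a[mutual, 1],
    uy_um = b[ia[mutual], 2] - a[mutual, 2],
    quality = 1 - sqrt(da[mutual]) / max_displacement
  )
  class(out) <- c("sparse_displacements", "data.frame")
  out
}

as_xy <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(all(c("x_um", "y_um") %in% names(p)))
    cbind(p$x_um, p$y_um)
  } else {
    stopifnot(is.matrix(p), ncol(p) >= 2)
    p[, 1:2, drop = FALSE]
  }
}

mean_nn_spacing <- function(a) {
  if (nrow(a) < 2) return(Inf)
  d2 <- outer(a[, 1], a[, 1], "-")^2 + outer(a[, 2], a[, 2], "-")^2
  diag(d2) <- Inf
  mean(sqrt(apply(d2, 1, min)))
}

#' Two-pass (predictor-corrector) bead linking
#'
#' Mutual-nearest-neighbour linking loses beads exactly where the science
#' happens: where the displacement approaches the bead spacing, the nearest
#' loaded bead is often the wrong one.  The corrector passes fix this with
#' the standard particle-tracking predictor-corrector scheme: the confident
#' first-pass vectors (after [filter_vector_outliers()]) define a thin-plate
#' displacement predictor; every unmatched reference bead is advected by the
#' predictor and linked to the closest free loaded bead within
#' `refine_radius` of its predicted position.  The pass is repeated (up to
#' `max_passes`), refitting the predictor each time, so an unmatched region
#' is recovered from its rim inward even where the displacement exceeds the
#' bead spacing.
#'
#' @inheritParams match_beads
#' @param refine_radius Search radius around the predicted position, um.
#' @param max_passes Maximum corrector passes (default 5).
#'
#' @return A `sparse_displacements` data.frame (see [match_beads()]),
#'   outlier-filtered.
#' @export
match_beads_predictive <- function(ref_positions, loaded_positions,
                                   max_displacement = NULL,
                                   refine_radius = 0.35, max_passes = 5) {
  a <- as_xy(ref_positions); b <- as_xy(loaded_positions)
  sp <- filter_vector_outliers(
    match_beads(ref_positions, loaded_positions, max_displacement)
  )
  for (pass in seq_len(max_passes)) {
    if (nrow(sp) < 12) return(sp)
    d2ref <- outer(a[, 1], sp$x_um, "-")^2 + outer(a[, 2], sp$y_um, "-")^2
    unmatched <- which(apply(d2ref, 1, min) > 1e-12)
    if (length(unmatched) == 0) break
    pred <- tps_predict(sp, a[unmatched, 1], a[unmatched, 2])
    # loaded beads not yet claimed by an accepted link
    claimed_x <- sp$x_um + sp$ux_um
    claimed_y <- sp$y_um + sp$uy_um
    d2cl <- outer(b[, 1], claimed_x, "-")^2 + outer(b[, 2], claimed_y, "-")^2
    free <- which(apply(d2cl, 1, min) > 1e-12)
    if (length(free) == 0) break
    px <- a[unmatched, 1] + pred[, 1]
    py <- a[unmatched, 2] + pred[, 2]
    d2 <- outer(px, b[free, 1], "-")^2 + outer(py, b[free, 2], "-")^2
    jb <- max.col(-d2, ties.method = "first")
    ok <- d2[cbind(seq_along(unmatched), jb)] <= refine_radius^2
    if (!any(ok)) break
    add <- data.frame(
      x_um = a[unmatched[ok], 1],
      y_um = a[unmatched[ok], 2],
      ux_um = b[free[jb[ok]], 1] - a[unmatched[ok], 1],
      uy_um = b[free[jb[ok]], 2] - a[unmatched[ok], 2],
      quality = 1 - sqrt(d2[cbind(which(ok), jb[ok])]) / refine_radius
    )
    # corrector additions are validated by their distance to the model
    # prediction; re-running the global filter here would strip the very
    # steep-gradient vectors the corrector exists to recover
    out <- rbind(as.data.frame(sp), add)
    class(out) <- c("sparse_displacements", "data.frame")
    sp <- out
  }
  sp
}

# thin-plate prediction of (ux, uy) at query points from sparse vectors
tps_predict <- function(sp, qx, qy) {
  np <- nrow(sp)
  sc <- sqrt((diff(range(sp$x_um)) + 1) * (diff(range(sp$y_um)) + 1) / np)
  x <- sp$x_um / sc; y <- sp$y_um / sc
  r2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  amat <- rbind(cbind(tps_phi(r2), 1, x, y),
                cbind(t(cbind(1, x, y)), matrix(0, 3, 3)))
  sol <- solve(amat, rbind(cbind(sp$ux_um, sp$uy_um), matrix(0, 3, 2)))
  qx <- qx / sc; qy <- qy / sc
  r2q <- outer(qx, x, "-")^2 + outer(qy, y, "-")^2
  cbind(tps_phi(r2q), 1, qx, qy) %*% sol
}

#' Reject spurious displacement vectors by the normalized median test
#'
#' Particle-tracking occasionally produces gross mismatches (merged or
#' swapped beads) whose vectors differ wildly from their surroundings; a
#' single such vector can dominate an exact interpolation.  Following the
#' universal outlier detection of particle-image-velocimetry practice, each
#' vector is compared to the median vector of its `k` nearest neighbours and
#' dropped when its residual exceeds `threshold` times the neighbourhood's
#' median absolute residual plus a noise floor `eps_um`.  The test is
#' iterated (at most `max_iter` passes) because a removed gross outlier
#' tightens its neighbours' statistics.  In steep-gradient regions the test
#' deliberately errs on the side of rejection; the corrector passes of
#' [match_beads_predictive()] win falsely rejected beads back under a much
#' tighter, model-based validation.
#'
#' @param sparse A `sparse_displacements` data.frame.
#' @param k Neighbourhood size (default 10).
#' @param threshold Rejection threshold (default 2).
#' @param eps_um Measurement noise floor in um (default 0.01).
#' @param max_iter Maximum filter passes (default 3).
#'
#' @return The filtered `sparse_displacements`; the number of dropped
#'   vectors is recorded in `attr(, "n_rejected")`.
#' @export
filter_vector_outliers <- function(sparse, k = 10, threshold = 2,
                                   eps_um = 0.01, max_iter = 3) {
  total_rejected <- 0L
  for (pass in seq_len(max_iter)) {
    n <- nrow(sparse)
    if (n <= k + 3) break
    d2 <- outer(sparse$x_um, sparse$x_um, "-")^2 +
      outer(sparse$y_um, sparse$y_um, "-")^2
    diag(d2) <- Inf
    keep <- logical(n)
    for (i in seq_len(n)) {
      nb <- order(d2[i, ])[seq_len(k)]
      mux <- stats::median(sparse$ux_um[nb])
      muy <- stats::median(sparse$uy_um[nb])
      res_nb <- sqrt((sparse$ux_um[nb] - mux)^2 + (sparse$uy_um[nb] - muy)^2)
      res_i <- sqrt((sparse$ux_um[i] - mux)^2 + (sparse$uy_um[i] - muy)^2)
      keep[i] <- res_i <= threshold * (stats::median(res_nb) + eps_um)
    }
    sparse <- sparse[keep, , drop = FALSE]
    total_rejected <- total_rejected + sum(!keep)
    if (all(keep)) break
  }
  attr(sparse, "n_rejected") <- total_rejected
  sparse
}

#' Remove rigid stage drift using beads outside the cell
#'
#' Subtracts the median displacement vector of the beads lying outside the
#' cell mask (where the substrate should be at rest) from every bead.
#' Standard stage-drift correction for traction microscopy time series; a
#' no-op when no mask is supplied.
#'
#' @param sparse A `sparse_displacements` data.frame from [match_beads()].
#' @param mask Optional [cell_mask()]; beads at nodes inside the mask are
#'   excluded from the drift estimate.
#'
#' @return The corrected `sparse_displacements`, with the removed drift in
#'   `attr(, "drift_um")`.
#' @export
correct_drift <- function(sparse, mask = NULL) {
  if (is.null(mask)) return(sparse)
  stopifnot(inherits(mask, "cell_mask"))
  inside <- mask_contains(mask, sparse$x_um, sparse$y_um)
  if (all(inside)) return(sparse)
  drift <- c(stats::median(sparse$ux_um[!inside]),
             stats::median(sparse$uy_um[!inside]))
  sparse$ux_um <- sparse$ux_um - drift[1]
  sparse$uy_um <- sparse$uy_um - drift[2]
  attr(sparse, "drift_um") <- drift
  sparse
}

#' Interpolate sparse bead displacements onto a uniform grid
#'
#' Produces the regular displacement grid that the Fourier traction solver
#' requires, by thin-plate spline interpolation of each displacement
#' component over the scattered bead positions.  With `smoothing = 0` the
#' spline passes exactly through every bead vector (no smoothing bias, which
#' matters because the inverse elastic problem amplifies any systematic
#' attenuation of the displacement field); a positive `smoothing` penalizes
#' bending energy and trades fidelity for noise suppression.  The thin-plate
#' interpolant reproduces constant and affine displacement fields exactly.
#' Nodes outside the convex hull of the bead positions take the spline's
#' natural extrapolation and are flagged `FALSE` in the validity mask.
#'
#' @param sparse A `sparse_displacements` data.frame (>= 3 non-collinear
#'   points).
#' @param grid_spacing Output node spacing, um.
#' @param extent Output window `c(xmin, xmax, ymin, ymax)` in um; default
#'   the bounding box of the bead positions.
#' @param smoothing Non-negative thin-plate smoothing parameter
#'   (dimensionless, on coordinates scaled to the mean bead spacing);
#'   0 (default) interpolates exactly.
#'
#' @return A [displacement_field()] whose `validity_mask` is `TRUE` inside
#'   the convex hull of the beads.
#' @export
interpolate_to_grid <- function(sparse, grid_spacing, extent = NULL,
                                smoothing = 0) {
  stopifnot(is.data.frame(sparse))
  stopifnot_scalar(grid_spacing, "grid_spacing", positive = TRUE)
  stopifnot_scalar(smoothing, "smoothing", nonneg = TRUE)
  px <- sparse$x_um; py <- sparse$y_um
  if (length(px) < 3) {
    stop("need at least 3 sparse displacement points", call. = FALSE)
  }
  if (qr(cbind(1, px, py))$rank < 3) {
    stop("sparse points are collinear; cannot interpolate a 2-D field",
         call. = FALSE)
  }
  if (is.null(extent)) extent <- c(range(px), range(py))
  xs <- seq(extent[1], extent[2], by = grid_spacing)
  ys <- seq(extent[3], extent[4], by = grid_spacing)
  m <- length(xs); n <- length(ys)
  np <- length(px)
  # condition the radial system on coordinates scaled to the mean spacing
  sc <- sqrt((diff(range(px)) + grid_spacing) *
             (diff(range(py)) + grid_spacing) / np)
  x <- px / sc; y <- py / sc
  r2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  kmat <- tps_phi(r2)
  pmat <- cbind(1, x, y)
  amat <- rbind(cbind(kmat + np * smoothing * diag(np), pmat),
                cbind(t(pmat), matrix(0, 3, 3)))
  rhs <- rbind(cbind(sparse$ux_um, sparse$uy_um), matrix(0, 3, 2))
  sol <- solve(amat, rhs)
  ux <- matrix(0, n, m); uy <- matrix(0, n, m)
  gy <- ys / sc
  for (jj in seq_len(m)) {
    gx <- xs[jj] / sc
    dx2 <- (gx - matrix(x, n, np, byrow = TRUE))^2 + outer(gy, y, "-")^2
    emat <- cbind(tps_phi(dx2), rep(1, n), rep(gx, n), gy)
    v <- emat %*% sol
    ux[, jj] <- v[, 1]; uy[, jj] <- v[, 2]
  }
  hull <- grDevices::chull(px, py)
  bnd <- cbind(px[c(hull, hull[1])], py[c(hull, hull[1])])
  g <- grid_coords(n, m, grid_spacing, c(xs[1], ys[1]))
  inside <- mgcv::in.out(bnd, cbind(as.vector(g$x), as.vector(g$y)))
  displacement_field(ux, uy, grid_spacing, origin = c(xs[1], ys[1]),
                     validity_mask = matrix(inside, n, m))
}

# thin-plate radial basis phi(r) = r^2 log r, as a function of r^2
tps_phi <- function(r2) {
  out <- 0.5 * r2 * log(r2)
  out[r2 == 0] <- 0
  out
}
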