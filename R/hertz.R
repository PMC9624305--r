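# AFM force-indentation analysis: Hertz (Sneddon) conical-tip fits and
# force-volume elasticity maps.
#
# Units: z in um, force in nN, spring constant in N/m (1 N/m = 1000 nN/um),
# moduli in Pa internally and kPa in assembled maps.

n_per_m_to_nn_per_um <- 1000

#' AFM force curve
#'
#' One approach force-distance curve: cantilever deflection force versus
#' z-piezo extension, with the cantilever calibration needed to convert the
#' curve into force versus sample indentation.
#'
#' @param z_piezo Strictly increasing z-piezo positions, um (approach
#'   towards the sample; contact happens at larger z).
#' @param deflection_force Measured force, nN; same length as `z_piezo`
#'   (>= 20 samples).
#' @param spring_constant Cantilever spring constant, N/m.
#' @param half_angle Cone half-opening angle of the tip in degrees
#'   (default 30).
#'
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z_piezo, deflection_force, spring_constant = 0.03,
                        half_angle = 30) {
  stopifnot(is.numeric(z_piezo), is.numeric(deflection_force),
            length(z_piezo) == length(deflection_force))
  if (length(z_piezo) < 20) {
    stop("force curve needs at least 20 samples", call. = FALSE)
  }
  if (any(diff(z_piezo) <= 0)) {
    stop("z_piezo must be strictly increasing on the approach", call. = FALSE)
  }
  stopifnot_scalar(spring_constant, "spring_constant", positive = TRUE)
  stopifnot_scalar(half_angle, "half_angle", positive = TRUE)
  structure(
    list(z_piezo = z_piezo, deflection_force = deflection_force,
         spring_constant = spring_constant, half_angle = half_angle),
    class = "force_curve"
  )
}

hertz_cone_coeff <- function(young_modulus_pa, half_angle, poisson) {
  # F[nN] = coeff * delta[um]^2 ; 1 Pa = 1e-3 nN/um^2
  (2 / pi) * tan(half_angle * pi / 180) *
    (young_modulus_pa * 1e-3) / (1 - poisson^2)
}

#' Locate the tip-sample contact point of a force curve
#'
#' Estimates the pre-contact force baseline (median of the early flat
#' segment) and its noise level, finds the first sustained crossing of
#' baseline + `noise_multiple` x noise, then refines the contact position by
#' a continuous piecewise fit: flat baseline before contact, quadratic
#' (conical Hertz) branch after, with the breakpoint minimizing the total
#' squared residual.  The earliest crossing is used to bracket the
#' refinement so the result is deterministic.
#'
#' @param curve A [force_curve()] with at least 10 pre-contact samples.
#' @param noise_multiple Detection threshold in units of baseline noise
#'   (default 5).
#' @param baseline_fraction Fraction of the earliest samples assumed
#'   contact-free for the initial baseline/noise estimate (default 0.2).
#'
#' @return A list with `contact_point_um` and `baseline_nn`.  A curve that
#'   never leaves its baseline raises a `not_in_contact` error.
#' @export
find_contact_point <- function(curve, noise_multiple = 5,
                               baseline_fraction = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z_piezo; f <- curve$deflection_force
  n <- length(z)
  nb <- max(10L, floor(baseline_fraction * n))
  if (nb >= n - 5) nb <- n - 5
  baseline <- stats::median(f[seq_len(nb)])
  noise <- stats::mad(f[seq_len(nb)])
  floor_thr <- 1e-3 * max(abs(f - baseline))
  thr <- baseline + max(noise_multiple * noise, floor_thr)
  above <- f > thr
  # sustained crossing: 3 consecutive samples above threshold
  sustained <- which(above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE))
  sustained <- sustained[sustained > nb]
  if (length(sustained) == 0 || max(abs(f - baseline)) <= 0) {
    stop(structure(
      class = c("not_in_contact", "error", "condition"),
      list(message = "tip never contacts the sample (flat force curve)",
           call = sys.call(-1))
    ))
  }
  i0 <- sustained[1]
  lo <- z[max(nb, i0 - 30L)]
  hi <- z[min(n - 10L, i0 + 5L)]
  ssr <- function(zc) piecewise_ssr(curve, zc)
  opt <- stats::optimize(ssr, lower = lo, upper = hi, tol = 1e-6)
  zc <- opt$minimum
  list(contact_point_um = zc,
       baseline_nn = mean(f[z < zc]))
}

# total SSR of flat-baseline + Hertz-quadratic model at contact candidate zc
piecewise_ssr <- function(curve, zc) {
  z <- curve$z_piezo; f <- curve$deflection_force
  pre <- z < zc
  if (sum(pre) < 3 || sum(!pre) < 3) return(Inf)
  b <- mean(f[pre])
  k <- curve$spring_constant * n_per_m_to_nn_per_um
  delta <- (z[!pre] - zc) - (f[!pre] - b) / k
  delta[delta < 0] <- 0
  d2 <- delta^2
  y <- f[!pre] - b
  cc <- sum(d2 * y) / sum(d2^2)
  if (!is.finite(cc)) return(Inf)
  sum((f[pre] - b)^2) + sum((y - cc * d2)^2)
}

#' Fit the Hertz model for a conical tip to a force curve
#'
#' Extracts the sample Young's modulus from the post-contact branch using
#' the Sneddon solution for a rigid cone indenting an elastic half-space,
#' \deqn{F = \frac{2}{\pi} \tan(\alpha) \frac{E}{1 - \nu^2} \delta^2,}
#' with `alpha` the cone half-angle and `nu` the cell Poisson ratio.  The
#' indentation is the piezo travel past contact corrected for cantilever
#' bending, `delta = (z - z_contact) - F / k` (correction on by default;
#' required for stiff levers to agree with soft ones).  `E` follows from a
#' linear least-squares fit of `F` on `delta^2`.  Fits are restricted to
#' `delta <= max_indentation` to stay in the small-deformation regime, and
#' flagged by quality control when the relative fit error exceeds
#' `qc_threshold`.
#'
#' @param curve A [force_curve()].
#' @param poisson_cell Poisson ratio of the cell (default 0.5,
#'   incompressible).
#' @param contact Optional result of [find_contact_point()]; computed when
#'   missing.
#' @param max_indentation Maximum indentation depth used in the fit, um
#'   (default 0.5, i.e. 10 percent of a nominal 5 um soma height).
#' @param bending_correction Subtract the cantilever deflection `F/k` from
#'   the indentation (default TRUE).
#' @param qc_threshold Relative fit error above which the fit is flagged
#'   (default 0.20).
#'
#' @return An object of class `hertz_fit`: `young_modulus_pa`,
#'   `contact_point_um`, `baseline_nn`, `rms_residual_nn`,
#'   `relative_fit_error` (rms residual / rms post-contact force),
#'   `converged`, `qc_pass`, `n_fit`.
#'   A curve that cannot be fitted (no contact, negative or non-finite
#'   modulus) returns `converged = FALSE` rather than raising, except for
#'   the explicit `not_in_contact` error from contact detection.
#' @export
fit_hertz_cone <- function(curve, poisson_cell = 0.5, contact = NULL,
                           max_indentation = 0.5, bending_correction = TRUE,
                           qc_threshold = 0.20) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(contact)) contact <- find_contact_point(curve)
  z <- curve$z_piezo
  f <- curve$deflection_force - contact$baseline_nn
  k <- curve$spring_constant * n_per_m_to_nn_per_um
  post <- z > contact$contact_point_um
  delta <- (z[post] - contact$contact_point_um)
  if (bending_correction) delta <- delta - f[post] / k
  keep <- delta > 0 & delta <= max_indentation
  failed <- structure(
    list(young_modulus_pa = NA_real_,
         contact_point_um = contact$contact_point_um,
         baseline_nn = contact$baseline_nn,
         rms_residual_nn = NA_real_, relative_fit_error = NA_real_,
         converged = FALSE, qc_pass = FALSE, n_fit = sum(keep)),
    class = "hertz_fit"
  )
  if (sum(keep) < 15) return(failed)
  d2 <- delta[keep]^2
  y <- f[post][keep]
  coeff <- sum(d2 * y) / sum(d2^2)
  alpha <- curve$half_angle
  e_pa <- coeff * pi * (1 - poisson_cell^2) / (2 * tan(alpha * pi / 180)) * 1e3
  if (!is.finite(e_pa) || e_pa <= 0) return(failed)
  res <- y - coeff * d2
  rms_res <- sqrt(mean(res^2))
  rel <- rms_res / sqrt(mean(y^2))
  structure(
    list(young_modulus_pa = e_pa,
         contact_point_um = contact$contact_point_um,
         baseline_nn = contact$baseline_nn,
         rms_residual_nn = rms_res, relative_fit_error = rel,
         converged = TRUE, qc_pass = rel <= qc_threshold, n_fit = sum(keep)),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<hertz_fit> E = %.0f Pa, contact %.3f um, rel. error %.1f%%%s\n",
      x$young_modulus_pa, x$contact_point_um, 100 * x$relative_fit_error,
      if (x$qc_pass) "" else " [QC FLAG]"
    ))
  } else {
    cat("<hertz_fit> not converged\n")
  }
  invisible(x)
}

#' Grid of force curves (force-volume measurement)
#'
#' @param curves List of [force_curve()] objects in row-major order
#'   (row 1 left-to-right, then row 2, ...).
#' @param nrow,ncol Grid dimensions; `nrow * ncol` must match
#'   `length(curves)`.
#' @param grid_spacing Lateral distance between curve positions, um.
#' @return An object of class `force_volume`.
#' @export
force_volume <- function(curves, nrow, ncol, grid_spacing = 1) {
  stopifnot(is.list(curves), length(curves) == nrow * ncol)
  stopifnot_scalar(grid_spacing, "grid_spacing", positive = TRUE)
  structure(
    list(curves = curves, nrow = as.integer(nrow), ncol = as.integer(ncol),
         grid_spacing = grid_spacing),
    class = "force_volume"
  )
}

#' Assemble an elasticity map from a force-volume grid
#'
#' Runs [fit_hertz_cone()] on every curve of the grid and collects the
#' fitted moduli (kPa) into a map with a quality-control mask: pixels whose
#' fit failed or exceeded the relative-error threshold are masked out.  When
#' more than half the fits fail the map is flagged unreliable (with a
#' warning) but still returned for inspection.
#'
#' @param fv A [force_volume()].
#' @param ... Passed to [fit_hertz_cone()] (e.g. `qc_threshold`,
#'   `poisson_cell`).
#'
#' @return An object of class `elasticity_map`: `moduli_kpa` (matrix, NA
#'   where unfitted), `qc_mask`, `grid_spacing`, `stats`
#'   (mean/min/max over QC-passing pixels), `unreliable`.
#' @export
build_elasticity_map <- function(fv, ...) {
  stopifnot(inherits(fv, "force_volume"))
  n <- fv$nrow; m <- fv$ncol
  moduli <- matrix(NA_real_, n, m)
  qc <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cv <- fv$curves[[(i - 1) * m + j]]
      fit <- tryCatch(fit_hertz_cone(cv, ...), not_in_contact = function(e) NULL)
      if (!is.null(fit) && fit$converged) {
        moduli[i, j] <- fit$young_modulus_pa / 1000
        qc[i, j] <- fit$qc_pass
      }
    }
  }
  unreliable <- mean(!qc) > 0.5
  if (unreliable) {
    warning("more than 50% of force-curve fits failed quality control; ",
            "elasticity map flagged unreliable", call. = FALSE)
  }
  stats <- if (any(qc)) {
    list(mean_kpa = mean(moduli[qc]), min_kpa = min(moduli[qc]),
         max_kpa = max(moduli[qc]))
  } else {
    list(mean_kpa = NA_real_, min_kpa = NA_real_, max_kpa = NA_real_)
  }
  structure(
    list(moduli_kpa = moduli, qc_mask = qc, grid_spacing = fv$grid_spacing,
         stats = stats, unreliable = unreliable),
    class = "elasticity_map"
  )
}

#' Construct an elasticity map directly from a modulus matrix
#'
#' Convenience constructor for maps obtained outside the force-volume
#' fitting path (e.g. imported data or synthetic truth).
#'
#' @param moduli_kpa Numeric matrix of moduli in kPa.
#' @param grid_spacing Pixel spacing in um.
#' @param qc_mask Logical matrix; default all TRUE where finite and > 0.
#' @return An `elasticity_map`.
#' @export
elasticity_map <- function(moduli_kpa, grid_spacing = 1, qc_mask = NULL) {
  stopifnot(is.matrix(moduli_kpa))
  if (is.null(qc_mask)) qc_mask <- is.finite(moduli_kpa) & moduli_kpa > 0
  stopifnot(all(dim(qc_mask) == dim(moduli_kpa)))
  stats <- list(mean_kpa = mean(moduli_kpa[qc_mask]),
                min_kpa = min(moduli_kpa[qc_mask]),
                max_kpa = max(moduli_kpa[qc_mask]))
  structure(
    list(moduli_kpa = moduli_kpa, qc_mask = qc_mask,
         grid_spacing = grid_spacing, stats = stats, unreliable = !any(qc_mask)),
    class = "elasticity_map"
  )
}

#' @export
print.elasticity_map <- function(x, ...) {
  cat(sprintf(
    "<elasticity_map> %d x %d px (h = %g um), mean %.2f kPa [%.2f, %.2f], %d/%d QC pass%s\n",
    nrow(x$moduli_kpa), ncol(x$moduli_kpa), x$grid_spacing,
    x$stats$mean_kpa, x$stats$min_kpa, x$stats$max_kpa,
    sum(x$qc_mask), length(x$qc_mask),
    if (isTRUE(x$unreliable)) " [UNRELIABLE]" else ""
  ))
  invisible(x)
}
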