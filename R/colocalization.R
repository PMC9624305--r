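# Overlap between stiff regions of the elasticity map and actin-rich
# regions of a registered fluorescence image.

#' Overlap of stiff map regions with high-actin regions
#'
#' Quantifies how much of the stiff part of a cell (elastic modulus at or
#' above `e_threshold`, quality-controlled pixels only) lies inside the
#' actin-rich part of a registered fluorescence image.  The actin mask is
#' obtained by thresholding the intensity image, by default with Otsu's
#' method (no manual intensity scale is assumed), alternatively at a fixed
#' fraction of the image maximum.  The headline number is
#' `100 * |stiff AND actin| / |stiff|`; the reverse fraction (actin pixels
#' that are stiff) is reported alongside.
#'
#' @param map An [elasticity map][build_elasticity_map] (kPa).
#' @param actin_image Intensity matrix already resampled to the map grid
#'   (registration is an input, not computed here).
#' @param e_threshold Stiffness threshold in kPa (default 1, the
#'   higher-than-average cutoff used for neuronal somas).
#' @param actin_rule `"otsu"` (default) or `"fraction"`.
#' @param fraction Threshold as a fraction of the maximum intensity when
#'   `actin_rule = "fraction"` (default 0.5).
#'
#' @return An object of class `overlap_result`: `overlap_percent`,
#'   `reverse_percent`, `stiff_pixel_count`, `actin_pixel_count`,
#'   `joint_count`, `e_threshold_kpa`, `intensity_threshold_rule`,
#'   `intensity_threshold_value`.
#'   An empty stiff mask is an error (the overlap is undefined).
#' @export
overlap_fraction <- function(map, actin_image, e_threshold = 1,
                             actin_rule = c("otsu", "fraction"),
                             fraction = 0.5) {
  stopifnot(inherits(map, "elasticity_map"), is.matrix(actin_image))
  if (!all(dim(actin_image) == dim(map$moduli_kpa))) {
    stop("actin image must be resampled to the elasticity map grid",
         call. = FALSE)
  }
  actin_rule <- match.arg(actin_rule)
  stopifnot_scalar(e_threshold, "e_threshold", positive = TRUE)
  stiff <- !is.na(map$moduli_kpa) & map$moduli_kpa >= e_threshold & map$qc_mask
  if (!any(stiff)) {
    stop("no stiff pixels at this threshold; overlap undefined", call. = FALSE)
  }
  thr <- actin_threshold(actin_image, actin_rule, fraction)
  actin <- actin_image >= thr
  joint <- sum(stiff & actin)
  structure(
    list(
      overlap_percent = 100 * joint / sum(stiff),
      reverse_percent = if (any(actin)) 100 * joint / sum(actin) else NA_real_,
      stiff_pixel_count = sum(stiff),
      actin_pixel_count = sum(actin),
      joint_count = joint,
      e_threshold_kpa = e_threshold,
      intensity_threshold_rule = actin_rule,
      intensity_threshold_value = thr
    ),
    class = "overlap_result"
  )
}

actin_threshold <- function(img, rule, fraction) {
  if (rule == "fraction") {
    stopifnot_scalar(fraction, "fraction", positive = TRUE)
    return(min(img) + fraction * (max(img) - min(img)))
  }
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(img, range = rng, levels = 256L)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %.1f%% of %d stiff px (>= %g kPa) inside actin mask (%d px, %s rule)\n",
    x$overlap_percent, x$stiff_pixel_count, x$e_threshold_kpa,
    x$actin_pixel_count, x$intensity_threshold_rule
  ))
  invisible(x)
}
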