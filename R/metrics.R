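# Per-cell traction summaries: forces, areas, time series, stiffness pairing.

#' Cell contact mask aligned to a gridded field
#'
#' @param mask Logical matrix, TRUE where the cell touches the substrate;
#'   same shape as the traction/displacement grids it will be applied to.
#' @param grid_spacing Node spacing in um; each node represents a
#'   `grid_spacing^2` um^2 patch of substrate.
#' @param label Cell identifier.
#' @param origin Physical coordinate of the first node, um.
#'
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(mask, grid_spacing, label = "cell", origin = c(0, 0)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  stopifnot_scalar(grid_spacing, "grid_spacing", positive = TRUE)
  structure(
    list(mask = mask, grid_spacing = grid_spacing,
         pixel_area = grid_spacing^2, label = as.character(label),
         origin = as.numeric(origin)),
    class = "cell_mask"
  )
}

mask_contains <- function(mask, x_um, y_um) {
  j <- round((x_um - mask$origin[1]) / mask$grid_spacing) + 1
  i <- round((y_um - mask$origin[2]) / mask$grid_spacing) + 1
  ok <- i >= 1 & i <= nrow(mask$mask) & j >= 1 & j <= ncol(mask$mask)
  out <- logical(length(x_um))
  out[ok] <- mask$mask[cbind(i[ok], j[ok])]
  out
}

#' Cell-substrate contact area
#'
#' @param mask A [cell_mask()]; must contain at least one TRUE node.
#' @return Contact area in um^2 (TRUE-node count times node area).
#' @export
contact_area <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  n <- sum(mask$mask)
  if (n == 0) stop("empty cell mask has no contact area", call. = FALSE)
  n * mask$pixel_area
}

#' Integrate a traction field over a cell contact area
#'
#' Turns the per-node stress field into the quantities usually reported per
#' cell: the total traction force magnitude `sum(|T|) * pixel_area` (the
#' scalar that grows with contractility even for a balanced force system),
#' the vector net force `sum(T) * pixel_area` (near zero for a mechanically
#' isolated cell), and the mean and peak stress over the contact mask.
#' Stresses in Pa and areas in um^2 combine to forces in nN via
#' `1 Pa um^2 = 1e-3 nN` ([pa_um2_to_nn]).
#'
#' @param traction A [traction_field()].
#' @param mask A [cell_mask()] of identical shape (non-empty).
#' @param time_min Optional acquisition time stamp in minutes.
#'
#' @return An object of class `cell_traction_summary`: a list with
#'   `mean_stress_pa`, `peak_stress_pa`, `total_force_nn`,
#'   `net_force_nn` (length-2 x/y), `contact_area_um2`, `time_min`, `label`.
#' @export
integrate_force <- function(traction, mask, time_min = NA_real_) {
  stopifnot(inherits(traction, "traction_field"), inherits(mask, "cell_mask"))
  if (!all(dim(traction$tx) == dim(mask$mask))) {
    stop("traction field and cell mask shapes differ", call. = FALSE)
  }
  if (!any(mask$mask)) stop("empty cell mask", call. = FALSE)
  mag <- field_magnitude(traction)
  sel <- mask$mask
  area <- mask$pixel_area
  structure(
    list(
      mean_stress_pa = mean(mag[sel]),
      peak_stress_pa = max(mag[sel]),
      total_force_nn = sum(mag[sel]) * area * pa_um2_to_nn,
      net_force_nn = c(sum(traction$tx[sel]), sum(traction$ty[sel])) *
        area * pa_um2_to_nn,
      contact_area_um2 = contact_area(mask),
      time_min = time_min,
      label = mask$label
    ),
    class = "cell_traction_summary"
  )
}

#' @export
print.cell_traction_summary <- function(x, ...) {
  cat(sprintf(
    "<cell_traction_summary> %s: mean %.1f Pa, peak %.1f Pa, F = %.2f nN over %.0f um^2\n",
    x$label, x$mean_stress_pa, x$peak_stress_pa, x$total_force_nn,
    x$contact_area_um2
  ))
  invisible(x)
}

#' Collapse per-cell summaries into a data frame
#'
#' @param summaries List of `cell_traction_summary` objects.
#' @return A data.frame with one row per summary (columns `cell`,
#'   `time_min`, `mean_stress_Pa`, `peak_stress_Pa`, `force_nN`,
#'   `net_fx_nN`, `net_fy_nN`, `area_um2`).
#' @export
summary_table <- function(summaries) {
  stopifnot(is.list(summaries))
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      cell = s$label, time_min = s$time_min,
      mean_stress_Pa = s$mean_stress_pa, peak_stress_Pa = s$peak_stress_pa,
      force_nN = s$total_force_nn,
      net_fx_nN = s$net_force_nn[1], net_fy_nN = s$net_force_nn[2],
      area_um2 = s$contact_area_um2
    )
  }))
}

#' Summarize a single-cell traction stress time series
#'
#' Collects the `(time, mean stress)` trace of one cell measured at
#' successive time points (10-minute intervals in the reference protocol)
#' and attaches descriptive statistics.  As a convenience the trace is
#' classified `"growing-like"` when the stress range (max - min) exceeds
#' `range_threshold_pa`, reflecting the intermittent high/low stress
#' alternation of actively growing cells, and `"quiescent-like"` otherwise;
#' the classification is heuristic, not a measurement.
#'
#' @param summaries List of `cell_traction_summary` objects with strictly
#'   increasing `time_min`.
#' @param range_threshold_pa Stress range separating the two labels
#'   (default 20 Pa).
#'
#' @return A list with `trace` (data.frame `time_min`, `mean_stress_Pa`),
#'   `stats` (`mean`, `sem`, `min`, `max` in Pa; `sem` is 0 with
#'   `sem_defined = FALSE` for a single point), and `classification`.
#' @export
summarize_time_series <- function(summaries, range_threshold_pa = 20) {
  stopifnot(is.list(summaries), length(summaries) >= 1)
  tt <- vapply(summaries, function(s) s$time_min, numeric(1))
  if (any(!is.finite(tt)) || any(diff(tt) <= 0)) {
    stop("summaries must carry strictly increasing time stamps", call. = FALSE)
  }
  ss <- vapply(summaries, function(s) s$mean_stress_pa, numeric(1))
  n <- length(ss)
  sem_defined <- n > 1
  list(
    trace = data.frame(time_min = tt, mean_stress_Pa = ss),
    stats = list(
      mean = mean(ss),
      sem = if (sem_defined) stats::sd(ss) / sqrt(n) else 0,
      sem_defined = sem_defined,
      min = min(ss), max = max(ss)
    ),
    classification = if (max(ss) - min(ss) > range_threshold_pa)
      "growing-like" else "quiescent-like",
    range_threshold_pa = range_threshold_pa
  )
}

#' Pair per-cell traction stress with AFM elastic modulus
#'
#' Joins traction summaries with elasticity maps by cell label, yielding the
#' table behind stress-stiffness coupling plots: one row per cell with the
#' mean traction stress (Pa, TFM) and the mean elastic modulus (kPa, AFM)
#' over quality-controlled map pixels.
#'
#' @param tfm_summaries List of `cell_traction_summary` objects.
#' @param elasticity_maps Named list of [elasticity maps][build_elasticity_map],
#'   names matching the summary labels.
#' @param growth_labels Optional named character vector of growth state per
#'   cell label.
#'
#' @return A data.frame with columns `cell`, `mean_stress_Pa`,
#'   `mean_modulus_kPa`, `growth_label`.
#' @export
pair_stress_modulus <- function(tfm_summaries, elasticity_maps,
                                growth_labels = NULL) {
  stopifnot(is.list(tfm_summaries), is.list(elasticity_maps))
  if (length(tfm_summaries) == 0) {
    return(data.frame(cell = character(0), mean_stress_Pa = numeric(0),
                      mean_modulus_kPa = numeric(0),
                      growth_label = character(0)))
  }
  rows <- lapply(tfm_summaries, function(s) {
    m <- elasticity_maps[[s$label]]
    if (is.null(m)) {
      stop(sprintf("no elasticity map for cell label '%s'", s$label),
           call. = FALSE)
    }
    stopifnot(inherits(m, "elasticity_map"))
    valid <- m$qc_mask
    data.frame(
      cell = s$label,
      mean_stress_Pa = s$mean_stress_pa,
      mean_modulus_kPa = mean(m$moduli_kpa[valid]),
      growth_label = if (is.null(growth_labels)) NA_character_
                     else unname(growth_labels[s$label])
    )
  })
  do.call(rbind, rows)
}
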