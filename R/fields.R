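#' Gridded substrate displacement field
#'
#' A two-component vector field `u = (ux, uy)` sampled on a uniform
#' rectangular grid, in micrometres.  `u(r) = r' - r` is the in-plane motion
#' of a substrate material point from its relaxed position `r` to its loaded
#' position `r'`.
#'
#' @param ux,uy Numeric matrices of identical shape with the x and y
#'   displacement components in um.
#' @param grid_spacing Node spacing in um (> 0).
#' @param origin Physical coordinate `(x0, y0)` of the first grid node
#'   (row 1, column 1), in um.
#' @param validity_mask Logical matrix marking nodes backed by measured
#'   (interpolated) data rather than extrapolation; defaults to all `TRUE`.
#'
#' @return An object of class `displacement_field`.
#' @seealso [traction_field()], [fttc_invert()], [interpolate_to_grid()]
#' @export
displacement_field <- function(ux, uy, grid_spacing, origin = c(0, 0),
                               validity_mask = NULL) {
  check_field_components(ux, uy, grid_spacing)
  if (is.null(validity_mask)) {
    validity_mask <- matrix(TRUE, nrow(ux), ncol(ux))
  }
  stopifnot(is.logical(validity_mask), all(dim(validity_mask) == dim(ux)))
  if (any(!is.finite(ux[validity_mask])) || any(!is.finite(uy[validity_mask]))) {
    stop("displacement components must be finite wherever validity_mask is TRUE",
         call. = FALSE)
  }
  structure(
    list(ux = ux, uy = uy, grid_spacing = grid_spacing,
         origin = as.numeric(origin), validity_mask = validity_mask),
    class = "displacement_field"
  )
}

#' Gridded traction stress field
#'
#' A two-component stress field `T = (tx, ty)` in Pa on a uniform rectangular
#' grid: the tangential force per unit area that the cell exerts on the
#' substrate surface at each node.
#'
#' @param tx,ty Numeric matrices of identical shape, traction components
#'   in Pa.
#' @inheritParams displacement_field
#' @param regularization_used Non-negative Tikhonov parameter that produced
#'   this field (0 for an unregularized inversion or a synthetic truth).
#'
#' @return An object of class `traction_field`.
#' @seealso [fttc_invert()], [forward_displacement()], [integrate_force()]
#' @export
traction_field <- function(tx, ty, grid_spacing, origin = c(0, 0),
                           regularization_used = 0) {
  check_field_components(tx, ty, grid_spacing)
  if (any(!is.finite(tx)) || any(!is.finite(ty))) {
    stop("traction components must be finite", call. = FALSE)
  }
  stopifnot_scalar(regularization_used, "regularization_used", nonneg = TRUE)
  structure(
    list(tx = tx, ty = ty, grid_spacing = grid_spacing,
         origin = as.numeric(origin),
         regularization_used = regularization_used),
    class = "traction_field"
  )
}

check_field_components <- function(a, b, grid_spacing) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    stop("field components must be matrices of identical shape", call. = FALSE)
  }
  stopifnot_scalar(grid_spacing, "grid_spacing", positive = TRUE)
  invisible(TRUE)
}

#' Traction magnitude map
#'
#' @param field A `traction_field` (or `displacement_field`).
#' @return Matrix of `sqrt(tx^2 + ty^2)` (or `sqrt(ux^2 + uy^2)`).
#' @export
field_magnitude <- function(field) {
  if (inherits(field, "traction_field")) {
    sqrt(field$tx^2 + field$ty^2)
  } else if (inherits(field, "displacement_field")) {
    sqrt(field$ux^2 + field$uy^2)
  } else {
    stop("expected a traction_field or displacement_field", call. = FALSE)
  }
}

#' @export
print.traction_field <- function(x, ...) {
  m <- field_magnitude(x)
  cat(sprintf(
    "<traction_field> %d x %d grid, h = %g um, |T| max %.3g Pa, lambda = %g\n",
    nrow(x$tx), ncol(x$tx), x$grid_spacing, max(m), x$regularization_used
  ))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- field_magnitude(x)
  cat(sprintf(
    "<displacement_field> %d x %d grid, h = %g um, |u| max %.3g um, %d/%d valid\n",
    nrow(x$ux), ncol(x$ux), x$grid_spacing, max(m),
    sum(x$validity_mask), length(x$validity_mask)
  ))
  invisible(x)
}

#' @export
as.data.frame.traction_field <- function(x, ...) {
  g <- grid_coords(nrow(x$tx), ncol(x$tx), x$grid_spacing, x$origin)
  data.frame(
    x_um = as.vector(g$x), y_um = as.vector(g$y),
    tx_Pa = as.vector(x$tx), ty_Pa = as.vector(x$ty)
  )
}

#' @export
as.data.frame.displacement_field <- function(x, ...) {
  g <- grid_coords(nrow(x$ux), ncol(x$ux), x$grid_spacing, x$origin)
  data.frame(
    x_um = as.vector(g$x), y_um = as.vector(g$y),
    ux_um = as.vector(x$ux), uy_um = as.vector(x$uy),
    valid = as.vector(x$validity_mask)
  )
}
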