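#' Mechanical properties of the elastic growth substrate
#'
#' Bundles the Young's modulus and Poisson ratio of the hydrogel on which the
#' cells grow.  The elastic model everywhere in this package is a
#' semi-infinite, homogeneous, isotropic half-space (the Boussinesq
#' approximation), appropriate for gels much thicker than the lateral scale
#' of the traction pattern.
#'
#' @param young_modulus Young's modulus of the gel in Pa.  Polyacrylamide
#'   gels used for neuronal traction microscopy are soft, typically a few
#'   hundred Pa; the default is 470 Pa.
#' @param poisson_ratio Poisson ratio, in `[0, 0.5]`.  Hydrogels are nearly
#'   incompressible, so the default is 0.5.
#'
#' @return An object of class `substrate_properties`.
#' @examples
#' substrate_properties(470)
#' @export
substrate_properties <- function(young_modulus = 470, poisson_ratio = 0.5) {
  stopifnot_scalar(young_modulus, "young_modulus", positive = TRUE)
  stopifnot_scalar(poisson_ratio, "poisson_ratio")
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    stop("`poisson_ratio` must be in [0, 0.5]", call. = FALSE)
  }
  structure(
    list(
      young_modulus = young_modulus,
      poisson_ratio = poisson_ratio,
      thickness_assumption = "semi-infinite half-space"
    ),
    class = "substrate_properties"
  )
}

#' @export
print.substrate_properties <- function(x, ...) {
  cat(sprintf(
    "<substrate_properties> E = %g Pa, poisson ratio = %g (%s)\n",
    x$young_modulus, x$poisson_ratio, x$thickness_assumption
  ))
  invisible(x)
}

as_substrate <- function(x) {
  if (inherits(x, "substrate_properties")) return(x)
  stop("expected a `substrate_properties` object", call. = FALSE)
}
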