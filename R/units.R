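# Internal unit system for the hydrodynamic modules: micrometres, seconds,
# piconewtons, with viscosity in Pa s.  This system is closed under the Stokes
# formulas (1 Pa s x 1 um x 1 um/s = 1e-12 N = 1 pN), so expressions such as
# 6*pi*mu*a*U can be evaluated verbatim with a in um, U in um/s, mu in Pa s
# and yield pN.  Diffusivities are accepted in cm^2/s at the interface and
# converted to um^2/s internally.  The chamber module works in cm and %atm.

#' Convert a diffusivity from cm^2/s to um^2/s
#' @param D_cm2_s diffusivity in cm^2/s
#' @return diffusivity in um^2/s
#' @keywords internal
cm2_to_um2 <- function(D_cm2_s) D_cm2_s * 1e8

#' Fluid properties
#'
#' Viscosity and solute diffusivity of the medium.  Defaults are water at
#' room temperature and the diffusivity of a small molecule such as oxygen.
#'
#' @param viscosity dynamic viscosity mu, Pa s
#' @param diffusivity solute diffusivity D, cm^2/s
#' @return an object of class `fluid_properties`
#' @examples
#' fluid_properties()
#' @export
fluid_properties <- function(viscosity = 1e-3, diffusivity = 1e-5) {
  stopifnot(is.numeric(viscosity), length(viscosity) == 1, viscosity > 0,
            is.numeric(diffusivity), length(diffusivity) == 1, diffusivity > 0)
  structure(
    list(viscosity = viscosity,
         diffusivity = diffusivity,
         diffusivity_um2 = cm2_to_um2(diffusivity)),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid: mu =", x$viscosity, "Pa s,  D =", x$diffusivity, "cm^2/s\n")
  invisible(x)
}

## small vector helpers used throughout
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) v / vnorm(v)

assert_unit <- function(v, name, tol = 1e-9) {
  if (abs(vnorm(v) - 1) > tol) {
    stop(sprintf("`%s` must be a unit vector (|%s| = %.3g)", name, name, vnorm(v)),
         call. = FALSE)
  }
  invisible(v)
}
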