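# Advection-versus-diffusion scalings for a filter-feeding cell.
#
# A point-forced cell moves the fluid at speed u ~ f0 / (8 pi mu r), giving
# an advective nutrient flux j_a ~ u c ~ f0 c / (8 pi mu r); diffusion
# supplies j_d ~ D c / r.  Their ratio is independent of r:
#
#   Pe = j_a / j_d = f0 / (8 pi D mu),
#
# so 8 pi D mu acts as a "diffusive force" f_d that a cell must exceed to
# reshape its chemical environment.  With D = 1e-5 cm^2/s and mu = 1e-3 Pa s,
# f_d ~ 25 pN; cells exerting ~40 pN operate at Pe ~ 2.

#' Stokes drag force of a swimming sphere
#'
#' 6 pi mu a U, the force needed to pull a sphere of radius `a` through the
#' fluid at speed `U` - and hence the propulsive force inferred from a cell's
#' free-swimming speed.
#'
#' @param radius cell radius a (um)
#' @param speed swim speed U (um/s)
#' @param fluid a [fluid_properties()]
#' @return force in pN
#' @examples
#' stokes_force(4.25, 500)   # ~40 pN
#' @export
stokes_force <- function(radius, speed, fluid = fluid_properties()) {
  stopifnot(radius > 0, speed >= 0)
  6 * pi * fluid$viscosity * radius * speed
}

#' Diffusive force scale
#'
#' f_d = 8 pi D mu, the force scale below which diffusion erases the
#' nutrient gradients a cell's feeding current builds.
#'
#' @param fluid a [fluid_properties()]
#' @return force in pN
#' @examples
#' diffusive_force()   # ~25 pN
#' @export
diffusive_force <- function(fluid = fluid_properties()) {
  8 * pi * fluid$diffusivity_um2 * fluid$viscosity
}

#' Peclet number of a point-forced feeder
#'
#' Pe = f0 / (8 pi D mu), the ratio of advective to diffusive nutrient flux.
#'
#' @param f0 propulsive force (pN)
#' @param fluid a [fluid_properties()]
#' @return dimensionless Peclet number
#' @examples
#' peclet(40)   # ~1.6, i.e. about 2
#' @export
peclet <- function(f0, fluid = fluid_properties()) {
  stopifnot(f0 > 0)
  f0 / diffusive_force(fluid)
}

#' Feeding scaling report
#'
#' Computes the full set of feeding scalings for an organism preset or for
#' explicit parameters: the Stokes force estimate from the swim speed, the
#' diffusive force, and the Peclet number of the exerted force.  For presets
#' whose rounded characteristic force differs from the raw Stokes estimate,
#' both numbers are reported.
#'
#' @param organism optional preset name passed to [organism_preset()]
#' @param radius cell radius (um); ignored if `organism` given
#' @param speed swim speed (um/s); ignored if `organism` given
#' @param f0 propulsive force (pN); defaults to the Stokes estimate
#' @param fluid a [fluid_properties()]
#' @return a one-row [tibble::tibble()] with columns `organism`,
#'   `radius_um`, `speed_um_s`, `stokes_force_pN`, `force_pN`,
#'   `diffusive_force_pN`, `peclet`
#' @examples
#' scaling_report("thiovulum")
#' @export
scaling_report <- function(organism = NULL, radius = NULL, speed = NULL,
                           f0 = NULL, fluid = fluid_properties()) {
  if (!is.null(organism)) {
    p <- organism_preset(organism)
    radius <- p$radius
    speed <- p$swim_speed
    if (is.null(f0)) f0 <- p$force
    label <- p$name
  } else {
    stopifnot(!is.null(radius), !is.null(speed))
    label <- "custom"
  }
  fs <- stokes_force(radius, speed, fluid)
  if (is.null(f0)) f0 <- fs
  fd <- diffusive_force(fluid)
  tibble::tibble(
    organism = label,
    radius_um = radius,
    speed_um_s = speed,
    stokes_force_pN = fs,
    force_pN = f0,
    diffusive_force_pN = fd,
    peclet = f0 / fd
  )
}
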