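# Organism presets for the two veil formers: the sulfur bacterium
# Thiovulum majus and the ciliate Uronemella.  Values are the characteristic
# numbers of the two organisms; `force` is the rounded propulsive force and
# `stokes_force_estimate` the raw 6 pi mu a U estimate from the preset radius
# and swim speed (the two differ slightly for Uronemella, and both are kept).

.PRESETS <- list(
  thiovulum = list(
    name = "thiovulum",
    diameter = 8.5,          # um
    radius = 4.25,           # um
    aspect = 1.3,
    force = 40,              # pN, propulsive
    swim_speed = 500,        # um/s
    preferred_o2 = 4,        # % of atmospheric saturation
    elongation_rate = 0.65   # um/s, stalk growth
  ),
  uronemella = list(
    name = "uronemella",
    diameter = 25,
    radius = 12.5,
    aspect = 2,
    force = 50,
    swim_speed = 250,
    preferred_o2 = 7,
    elongation_rate = 1.5
  )
)

#' Organism preset
#'
#' Characteristic parameters of the two stalk-tethered veil formers:
#' `"thiovulum"` (the sulfur bacterium *Thiovulum majus*) and `"uronemella"`
#' (the ciliate *Uronemella*).
#'
#' @param name `"thiovulum"` or `"uronemella"`
#' @return a list with fields `diameter`, `radius` (um), `aspect`, `force`
#'   (pN), `swim_speed` (um/s), `preferred_o2` (% atm), `elongation_rate`
#'   (um/s), `geometry` (a [cell_geometry()] with semi-major axis equal to
#'   the preset radius), and `stokes_force_estimate` (pN, 6 pi mu a U at the
#'   default viscosity).
#' @examples
#' organism_preset("thiovulum")$force
#' @export
organism_preset <- function(name = c("thiovulum", "uronemella")) {
  name <- match.arg(name)
  p <- .PRESETS[[name]]
  p$geometry <- cell_geometry(p$radius, p$radius / p$aspect)
  p$stokes_force_estimate <- stokes_force(p$radius, p$swim_speed)
  p
}
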