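# Resistance functions of a prolate spheroid in Stokes flow.
#
# Closed forms follow the classical Oberbeck/Perrin results, written in terms
# of the eccentricity e and L = log((1+e)/(1-e)), and normalized here by the
# SEMI-MAJOR axis a:
#
#   drag force  F = 6 pi mu a alpha U,   torque  T = 8 pi mu a^3 beta omega,
#
#   alpha_par  = (8/3)  e^3 / (-2e + (1+e^2) L)
#   alpha_perp = (16/3) e^3 / ( 2e + (3e^2-1) L)
#   beta_par   = (4/3)  e^3 (1-e^2) / (2e - (1-e^2) L)
#   beta_perp  = (4/3)  e^3 (2-e^2) / (-2e + (1+e^2) L)
#
# All four tend to 1 in the sphere limit, recovering 6 pi mu a U and
# 8 pi mu a^3 omega.  Near e = 0 the denominators suffer catastrophic
# cancellation (three leading orders cancel, so double precision loses
# ~eps/e^2 relative accuracy); below ECC_SERIES_CUTOFF they are replaced by
# their series, which at the cutoff are accurate to O(e^6) ~ 1e-12 relative
#   -2e + (1+e^2)L = (8/3)e^3 + (16/15)e^5 + (24/35)e^7 + ...
#    2e + (3e^2-1)L = (16/3)e^3 + (8/5)e^5 + (36/35)e^7 + ...
#    2e - (1-e^2)L  = (4/3)e^3 + (4/15)e^5 + (4/35)e^7 + ...

ECC_SERIES_CUTOFF <- 1e-2

#' Cell geometry: a prolate spheroid
#'
#' @param semi_major semi-major axis a (um)
#' @param semi_minor semi-minor axis b (um); must satisfy b <= a
#' @return an object of class `cell_geometry` with fields `semi_major`,
#'   `semi_minor`, `aspect`
#' @examples
#' cell_geometry(12.5, 6.25)   # aspect ratio 2
#' @export
cell_geometry <- function(semi_major, semi_minor) {
  stopifnot(is.numeric(semi_major), is.numeric(semi_minor),
            length(semi_major) == 1, length(semi_minor) == 1)
  if (!(semi_minor > 0)) stop("semi_minor must be > 0", call. = FALSE)
  if (semi_major < semi_minor) {
    stop("oblate geometry (semi_major < semi_minor) is not supported",
         call. = FALSE)
  }
  structure(
    list(semi_major = semi_major, semi_minor = semi_minor,
         aspect = semi_major / semi_minor),
    class = "cell_geometry"
  )
}

#' Construct a geometry from an aspect ratio
#'
#' Semi-major axis defaults to 1 um so that lengths derived from the
#' coefficients (e.g. the critical stalk length) come out per unit a.
#'
#' @param aspect aspect ratio a/b >= 1
#' @param semi_major semi-major axis a (um)
#' @return a `cell_geometry`
#' @export
aspect_geometry <- function(aspect, semi_major = 1) {
  cell_geometry(semi_major, semi_major / aspect)
}

#' Eccentricity of a prolate spheroid
#'
#' @param geom a `cell_geometry`
#' @return e = sqrt(1 - (b/a)^2) in [0, 1)
#' @examples
#' eccentricity(aspect_geometry(2))   # 0.866
#' @export
eccentricity <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  sqrt(max(0, 1 - (geom$semi_minor / geom$semi_major)^2))
}

## denominators of the resistance functions, series-protected near e = 0
.drag_denominators <- function(e) {
  if (e < ECC_SERIES_CUTOFF) {
    list(
      d_tr_par  = (8 / 3) * e^3 + (16 / 15) * e^5 + (24 / 35) * e^7,
      d_tr_perp = (16 / 3) * e^3 + (8 / 5) * e^5 + (36 / 35) * e^7,
      d_rot_par = (4 / 3) * e^3 + (4 / 15) * e^5 + (4 / 35) * e^7
    )
  } else {
    L <- log((1 + e) / (1 - e))
    list(
      d_tr_par  = -2 * e + (1 + e^2) * L,
      d_tr_perp =  2 * e + (3 * e^2 - 1) * L,
      d_rot_par =  2 * e - (1 - e^2) * L
    )
  }
}

#' Translational resistance coefficients
#'
#' Dimensionless factors alpha such that the drag on the spheroid moving at
#' velocity U parallel (perpendicular) to its symmetry axis is
#' 6 pi mu a alpha U, with a the semi-major axis.
#'
#' @param geom a `cell_geometry`
#' @return named vector `c(alpha_par, alpha_perp)`
#' @examples
#' round(translational_coefficients(aspect_geometry(1.3)), 2)  # 0.82 0.86
#' @export
translational_coefficients <- function(geom) {
  e <- eccentricity(geom)
  if (e == 0) return(c(alpha_par = 1, alpha_perp = 1))
  d <- .drag_denominators(e)
  c(alpha_par  = (8 / 3) * e^3 / d$d_tr_par,
    alpha_perp = (16 / 3) * e^3 / d$d_tr_perp)
}

#' Rotational resistance coefficients
#'
#' Dimensionless factors beta such that the torque on the spheroid rotating
#' at angular velocity omega about (parallel) or transverse (perpendicular)
#' to its symmetry axis is 8 pi mu a^3 beta omega.
#'
#' @param geom a `cell_geometry`
#' @return named vector `c(beta_par, beta_perp)`
#' @examples
#' round(rotational_coefficients(aspect_geometry(2)), 2)  # 0.20 0.38
#' @export
rotational_coefficients <- function(geom) {
  e <- eccentricity(geom)
  if (e == 0) return(c(beta_par = 1, beta_perp = 1))
  d <- .drag_denominators(e)
  c(beta_par  = (4 / 3) * e^3 * (1 - e^2) / d$d_rot_par,
    beta_perp = (4 / 3) * e^3 * (2 - e^2) / d$d_tr_par)
}

#' Shape factor Gamma
#'
#' Gamma = (a^2 - b^2)/(a^2 + b^2), the factor controlling how the ambient
#' rate of strain rotates a spheroid (0 for a sphere, -> 1 for a needle).
#'
#' @param geom a `cell_geometry`
#' @return Gamma in [0, 1)
#' @examples
#' shape_factor(aspect_geometry(2))    # 0.6
#' @export
shape_factor <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  a2 <- geom$semi_major^2
  b2 <- geom$semi_minor^2
  (a2 - b2) / (a2 + b2)
}

#' All drag coefficients of a geometry
#'
#' @param geom a `cell_geometry`
#' @return an object of class `drag_coefficients` with fields `alpha_par`,
#'   `alpha_perp`, `beta_par`, `beta_perp`, `gamma`
#' @examples
#' drag_coefficients(aspect_geometry(1.3))
#' @export
drag_coefficients <- function(geom) {
  al <- translational_coefficients(geom)
  be <- rotational_coefficients(geom)
  structure(
    list(alpha_par = unname(al["alpha_par"]),
         alpha_perp = unname(al["alpha_perp"]),
         beta_par = unname(be["beta_par"]),
         beta_perp = unname(be["beta_perp"]),
         gamma = shape_factor(geom)),
    class = "drag_coefficients"
  )
}

#' @export
print.drag_coefficients <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Prolate-spheroid drag: alpha_par=%.*f alpha_perp=%.*f beta_par=%.*f beta_perp=%.*f gamma=%.*f\n",
    digits, x$alpha_par, digits, x$alpha_perp, digits, x$beta_par,
    digits, x$beta_perp, digits, x$gamma))
  invisible(x)
}

#' Orientation-dependent drag tensor
#'
#' Builds the symmetric tensor s_par d d^T + s_perp (I - d d^T) whose
#' eigenvector along the orientation d has eigenvalue s_par and whose
#' transverse eigenvalues are s_perp.  With the translational coefficients
#' this is the tensor A, with the rotational ones the tensor B.
#'
#' @param orientation unit 3-vector d
#' @param scalar_par eigenvalue along `orientation`
#' @param scalar_perp transverse eigenvalue
#' @return a 3x3 symmetric matrix
#' @examples
#' drag_tensor(c(0, 0, 1), 0.82, 0.86)
#' @export
drag_tensor <- function(orientation, scalar_par, scalar_perp) {
  stopifnot(is.numeric(orientation), length(orientation) == 3)
  assert_unit(orientation, "orientation")
  dd <- tcrossprod(orientation)
  scalar_par * dd + scalar_perp * (diag(3) - dd)
}
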