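# Stokeslet flow near a no-slip plane wall.
#
# The fluid occupies z > 0; the wall is z = 0.  A point force F (pN) applied
# to the fluid at x0 = (x, y, h), h > 0, drives the free-space (Oseen) flow
#
#   u_i(x) = (1 / 8 pi mu) (delta_ij / r + r_i r_j / r^3) F_j,   r = x - x0.
#
# The wall is accounted for by an image system beneath the plane, at the
# reflected point x0* = (x, y, -h).  Two modes are provided:
#
#   leading - only the sign-reversed stokeslet at x0* (the "image cell").
#             This captures the dominant back flow off the wall but leaves a
#             residual slip on z = 0.
#   blake   - the full image system (sign-reversed stokeslet plus stokeslet
#             doublet and source doublet), for which the total velocity
#             vanishes identically on the wall.  Writing R = x - x0*,
#             beta_k = (1, 1, -1), the doublet corrections are
#
#     u_i += (F_k / 8 pi mu) 2 h beta_k d/dR_k [ h R_i/R^3
#                                               - delta_i3/R - R_i R_3/R^3 ].
#
# All gradients (for the angular velocity and rate of strain of the ambient
# flow) are coded analytically and checked against finite differences in the
# test-suite.

#' Point force in the half-space above a wall
#'
#' @param position 3-vector (um); the z-component (height above the wall)
#'   must be positive
#' @param force 3-vector (pN) applied to the fluid
#' @return an object of class `point_force`
#' @examples
#' point_force(c(0, 0, 50), c(0, 0, -40))
#' @export
point_force <- function(position, force) {
  stopifnot(is.numeric(position), length(position) == 3,
            is.numeric(force), length(force) == 3)
  if (!(position[3] > 0)) {
    stop("the source must lie above the wall (position[3] > 0)", call. = FALSE)
  }
  structure(list(position = as.numeric(position), force = as.numeric(force)),
            class = "point_force")
}

## Oseen tensor velocity of a stokeslet with force F at the origin,
## evaluated at displacement r
.oseen_u <- function(r, F, mu) {
  rn <- vnorm(r)
  (F / rn + r * sum(r * F) / rn^3) / (8 * pi * mu)
}

## gradient d u_i / d x_l of the same field; returns 3x3 matrix J[i, l]
.oseen_grad <- function(r, F, mu) {
  rn <- vnorm(r)
  rF <- sum(r * F)
  J <- matrix(0, 3, 3)
  for (i in 1:3) for (l in 1:3) {
    J[i, l] <- (-F[i] * r[l] / rn^3 +
                  (F[l] * r[i] + (i == l) * rF) / rn^3 -
                  3 * r[i] * rF * r[l] / rn^5)
  }
  J / (8 * pi * mu)
}

## Blake doublet correction: velocity (and optionally gradient) at
## displacement R from the image point, for source height h and force F.
.blake_correction <- function(R, F, h, mu, gradient = FALSE) {
  Rn <- vnorm(R)
  beta <- c(1, 1, -1)
  u <- numeric(3)
  J <- if (gradient) matrix(0, 3, 3) else NULL
  for (i in 1:3) for (k in 1:3) {
    T1 <- (i == k) / Rn^3 - 3 * R[i] * R[k] / Rn^5
    T2 <- R[k] / Rn^3
    T3 <- ((i == k) * R[3] + (k == 3) * R[i]) / Rn^3 - 3 * R[i] * R[3] * R[k] / Rn^5
    u[i] <- u[i] + F[k] * 2 * h * beta[k] * (h * T1 + (i == 3) * T2 - T3)
    if (gradient) {
      for (l in 1:3) {
        dT1 <- (-3 * ((i == k) * R[l] + (i == l) * R[k] + (k == l) * R[i]) / Rn^5 +
                  15 * R[i] * R[k] * R[l] / Rn^7)
        dT2 <- (k == l) / Rn^3 - 3 * R[k] * R[l] / Rn^5
        dT3 <- (((i == k) * (l == 3) + (k == 3) * (i == l)) / Rn^3 -
                  3 * ((i == k) * R[3] + (k == 3) * R[i]) * R[l] / Rn^5 -
                  3 * ((i == l) * R[3] * R[k] + (l == 3) * R[i] * R[k] +
                         (k == l) * R[i] * R[3]) / Rn^5 +
                  15 * R[i] * R[3] * R[k] * R[l] / Rn^7)
        J[i, l] <- J[i, l] + F[k] * 2 * h * beta[k] * (h * dT1 + (i == 3) * dT2 - dT3)
      }
    }
  }
  list(u = u / (8 * pi * mu), J = if (gradient) J / (8 * pi * mu) else NULL)
}

#' Free-space stokeslet velocity
#'
#' @param force a [point_force()]
#' @param eval_point 3-vector (um), distinct from the source position
#' @param fluid a [fluid_properties()]
#' @return velocity 3-vector (um/s)
#' @examples
#' f <- point_force(c(0, 0, 100), c(0, 0, 40))
#' stokeslet(f, c(0, 0, 110))
#' @export
stokeslet <- function(force, eval_point, fluid = fluid_properties()) {
  stopifnot(inherits(force, "point_force"), length(eval_point) == 3)
  r <- eval_point - force$position
  if (vnorm(r) == 0) {
    stop("cannot evaluate the stokeslet at its singular point", call. = FALSE)
  }
  .oseen_u(r, force$force, fluid$viscosity)
}

#' Image-system velocity beneath a no-slip wall
#'
#' The velocity of the image singularities alone (the total flow is this
#' plus [stokeslet()]).  `mode = "leading"` keeps only the sign-reversed
#' stokeslet at the reflected point; `mode = "blake"` adds the stokeslet- and
#' source-doublet corrections so the total flow vanishes on z = 0.
#'
#' @param force a [point_force()]
#' @param eval_point 3-vector (um) with z >= 0
#' @param fluid a [fluid_properties()]
#' @param mode `"leading"` or `"blake"`
#' @return velocity 3-vector (um/s)
#' @export
image_system <- function(force, eval_point, fluid = fluid_properties(),
                         mode = c("leading", "blake")) {
  mode <- match.arg(mode)
  stopifnot(inherits(force, "point_force"), length(eval_point) == 3)
  h <- force$position[3]
  xs <- c(force$position[1], force$position[2], -h)
  R <- eval_point - xs
  u <- .oseen_u(R, -force$force, fluid$viscosity)
  if (mode == "blake") {
    u <- u + .blake_correction(R, force$force, h, fluid$viscosity)$u
  }
  u
}

#' Total velocity (stokeslet plus image system)
#'
#' @inheritParams image_system
#' @return velocity 3-vector (um/s)
#' @export
wall_velocity <- function(force, eval_point, fluid = fluid_properties(),
                          mode = c("leading", "blake")) {
  mode <- match.arg(mode)
  stokeslet(force, eval_point, fluid) + image_system(force, eval_point, fluid, mode)
}

#' Ambient flow experienced by the forcing cell
#'
#' Velocity, angular velocity and rate of strain of the image-system flow
#' (the cell's own unbounded stokeslet exerts no net force or torque on
#' itself and is excluded).  Gradients are analytic: Omega = curl(u)/2 and
#' E = (grad u + grad u^T)/2.
#'
#' @param force a [point_force()]
#' @param eval_point 3-vector (um); defaults to the source position
#' @param fluid a [fluid_properties()]
#' @param mode `"leading"` or `"blake"`
#' @return an object of class `ambient_flow`: list with `u` (um/s),
#'   `Omega` (1/s), `E` (3x3, 1/s)
#' @examples
#' f <- point_force(c(0, 0, 50), c(0, 0, -40))
#' ambient_at(f)
#' @export
ambient_at <- function(force, eval_point = force$position,
                       fluid = fluid_properties(),
                       mode = c("leading", "blake")) {
  mode <- match.arg(mode)
  stopifnot(inherits(force, "point_force"), length(eval_point) == 3)
  mu <- fluid$viscosity
  h <- force$position[3]
  xs <- c(force$position[1], force$position[2], -h)
  R <- eval_point - xs
  u <- .oseen_u(R, -force$force, mu)
  J <- .oseen_grad(R, -force$force, mu)
  if (mode == "blake") {
    bc <- .blake_correction(R, force$force, h, mu, gradient = TRUE)
    u <- u + bc$u
    J <- J + bc$J
  }
  Omega <- 0.5 * c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
  E <- 0.5 * (J + t(J))
  structure(list(u = u, Omega = Omega, E = E, mode = mode),
            class = "ambient_flow")
}

#' Uniform ambient flow (no rotation or strain)
#'
#' Convenience constructor used when exercising the orientation dynamics
#' under a prescribed flow rather than the image flow.
#'
#' @param u velocity 3-vector (um/s)
#' @param Omega angular velocity 3-vector (1/s)
#' @param E symmetric trace-free 3x3 rate-of-strain tensor (1/s)
#' @return an `ambient_flow`
#' @export
uniform_flow <- function(u = c(0, 0, 0), Omega = c(0, 0, 0),
                         E = matrix(0, 3, 3)) {
  stopifnot(length(u) == 3, length(Omega) == 3, all(dim(E) == c(3, 3)))
  if (abs(sum(diag(E))) > 1e-9) stop("E must be trace-free", call. = FALSE)
  structure(list(u = as.numeric(u), Omega = as.numeric(Omega), E = E,
                 mode = "uniform"),
            class = "ambient_flow")
}

#' Fitted power-law decay exponent of a flow field
#'
#' Least-squares slope of log|u| against log r for a sampler |u|(r).  A
#' stalked cell (sampled at a << r << l) decays with slope -1; a cell at
#' wall height decays with slope -3 (its stokeslet and image nearly cancel).
#'
#' @param sampler function of distance r returning the speed |u| at r
#' @param r_min,r_max sampling range (um)
#' @param n_points number of logarithmically spaced samples (>= 3)
#' @return fitted slope (dimensionless)
#' @examples
#' f <- point_force(c(0, 0, 1000), c(0, 0, -40))
#' s <- radial_speed_sampler(f, elevation = pi / 6)
#' decay_exponent(s, 20, 100)   # about -1
#' @export
decay_exponent <- function(sampler, r_min, r_max, n_points = 20) {
  stopifnot(r_min > 0, r_max > r_min)
  if (n_points < 3) stop("need at least 3 samples", call. = FALSE)
  r <- exp(seq(log(r_min), log(r_max), length.out = n_points))
  speed <- vapply(r, sampler, numeric(1))
  unname(stats::coef(stats::lm(log(speed) ~ log(r)))[2])
}

#' Speed sampler along a ray from a point force
#'
#' Returns a function of distance r giving |u| of the total wall-bounded
#' flow at the point `force$position + r * (cos(az) cos(el), sin(az) cos(el),
#' sin(el))`.
#'
#' @param force a [point_force()]
#' @param elevation angle above the wall plane (rad)
#' @param azimuth azimuthal angle (rad)
#' @param fluid a [fluid_properties()]
#' @param mode image mode (see [image_system()]); the full `"blake"` system
#'   is the default so that near-wall cancellations are captured
#' @return function r -> |u| (um/s)
#' @export
radial_speed_sampler <- function(force, elevation = pi / 6, azimuth = 0,
                                 fluid = fluid_properties(), mode = "blake") {
  dirv <- c(cos(azimuth) * cos(elevation), sin(azimuth) * cos(elevation),
            sin(elevation))
  function(r) vnorm(wall_velocity(force, force$position + r * dirv, fluid, mode))
}

#' Advect tracer particles in the wall-bounded flow
#'
#' Classical fourth-order Runge-Kutta integration of passive tracers in the
#' total (stokeslet + image) field, emulating streamline reconstruction from
#' tracer-particle movies.  Tracers are reflected at the wall if a step
#' undershoots z = 0 (the exact field cannot cross it; only discretization
#' can).
#'
#' @param force a [point_force()]
#' @param tracers n x 3 matrix of initial positions (um), all with z > 0
#' @param dt time step (s)
#' @param duration total time (s)
#' @param fluid a [fluid_properties()]
#' @param mode image mode, default `"blake"`
#' @return a [tibble::tibble()] track table with columns `track_id`, `time`,
#'   `x`, `y`, `z` (um)
#' @export
advect_tracers <- function(force, tracers, dt, duration,
                           fluid = fluid_properties(), mode = "blake") {
  tracers <- matrix(as.numeric(tracers), ncol = 3)
  stopifnot(dt > 0, duration >= dt, all(tracers[, 3] > 0))
  for (k in seq_len(nrow(tracers))) {
    if (vnorm(tracers[k, ] - force$position) == 0) {
      stop("tracer starts at the singular point", call. = FALSE)
    }
  }
  vel <- function(x) wall_velocity(force, x, fluid, mode)
  times <- seq(0, duration, by = dt)
  out <- vector("list", nrow(tracers))
  for (k in seq_len(nrow(tracers))) {
    x <- tracers[k, ]
    path <- matrix(NA_real_, length(times), 3)
    path[1, ] <- x
    for (s in seq_along(times)[-1]) {
      k1 <- vel(x)
      k2 <- vel(x + dt / 2 * k1)
      k3 <- vel(x + dt / 2 * k2)
      k4 <- vel(x + dt * k3)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (x[3] < 0) x[3] <- -x[3]
      path[s, ] <- x
    }
    out[[k]] <- tibble::tibble(track_id = k, time = times,
                               x = path[, 1], y = path[, 2], z = path[, 3])
  }
  do.call(rbind, out)
}
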