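# Orientation dynamics of a cell tethered to a wall by a rigid stalk.
#
# The cell sits at the end of a stalk of length l anchored at the origin of
# the wall plane; r_hat is the stalk direction, d_hat the cell's propulsive
# orientation.  The cell applies the force -f0 d_hat to the fluid (a cell
# oriented away from the wall pumps fluid toward it); the reaction f0 d_hat
# propels the cell.  The ambient flow it feels is the image-system flow of
# its own stokeslet evaluated at the cell position l r_hat.
#
# Stalk swing - torque balance about the anchor:
#     0 = r_hat x { f0 d_hat + 6 pi mu a A (u - l dr_hat/dt) },
# closed by a stalk-tension Lagrange multiplier along r_hat so that
# r_hat . dr_hat/dt = 0 (the component of the force balance along the stalk
# is carried by tension, not motion).
#
# Cell reorientation - torque-free condition on the cell:
#     dd_hat/dt = - d_hat x { 3 d_hat x A u + 4 a d_hat x B Omega
#                             + 4 a beta_perp Gamma (d_hat x E d_hat) }
#                 / ( a (3 alpha_perp + 4 beta_perp) ),
# with A, B the translational/rotational drag tensors and Gamma the shape
# factor.  When a is small the Omega and E terms drop and the cell simply
# aligns with the flow.
#
# The dynamics are integrated in Cartesian unit vectors (never in angles, to
# avoid coordinate singularities); the polar angles theta (of d_hat) and phi
# (of r_hat) are derived outputs.  By rotational symmetry about the wall
# normal the reduced (theta, phi) system carries the full dynamics.

#' Tethered-cell state
#'
#' @param stalk_direction unit 3-vector r_hat with positive z-component
#' @param cell_orientation unit 3-vector d_hat
#' @param stalk_length stalk length l (um), > 0
#' @return an object of class `tether_state` with derived angles `theta`,
#'   `phi` (polar angles of d_hat and r_hat from the wall normal) and `chi`,
#'   `xi` (their azimuths)
#' @examples
#' tether_state(c(0, 0, 1), c(sin(0.3), 0, cos(0.3)), 125)
#' @export
tether_state <- function(stalk_direction, cell_orientation, stalk_length) {
  stopifnot(length(stalk_direction) == 3, length(cell_orientation) == 3,
            is.numeric(stalk_length), stalk_length > 0)
  assert_unit(stalk_direction, "stalk_direction")
  assert_unit(cell_orientation, "cell_orientation")
  if (!(stalk_direction[3] > 0)) {
    stop("the cell must lie above the wall (stalk_direction[3] > 0)",
         call. = FALSE)
  }
  structure(
    list(stalk_direction = as.numeric(stalk_direction),
         cell_orientation = as.numeric(cell_orientation),
         stalk_length = stalk_length,
         theta = acos(min(1, max(-1, cell_orientation[3]))),
         phi = acos(min(1, max(-1, stalk_direction[3]))),
         chi = atan2(cell_orientation[2], cell_orientation[1]),
         xi = atan2(stalk_direction[2], stalk_direction[1])),
    class = "tether_state"
  )
}

#' Parameters of the tethered-cell dynamics
#'
#' @param geometry a [cell_geometry()]
#' @param f0 propulsive force (pN)
#' @param fluid a [fluid_properties()]
#' @param mode image-flow mode, `"leading"` (the image-cell approximation,
#'   the default) or `"blake"` (full image system)
#' @return an object of class `dynamics_params`, carrying the drag
#'   coefficients of the geometry
#' @examples
#' p <- organism_preset("uronemella")
#' dynamics_params(p$geometry, p$force)
#' @export
dynamics_params <- function(geometry, f0, fluid = fluid_properties(),
                            mode = c("leading", "blake")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "cell_geometry"), f0 > 0)
  structure(
    list(geometry = geometry, drag = drag_coefficients(geometry),
         fluid = fluid, f0 = f0, mode = mode),
    class = "dynamics_params"
  )
}

## apply the orientation tensors without materializing matrices
.apply_aniso <- function(v, dhat, s_par, s_perp) {
  proj <- sum(dhat * v)
  s_par * dhat * proj + s_perp * (v - dhat * proj)
}

#' Rate of change of the stalk direction
#'
#' Solves the anchor torque balance for dr_hat/dt, resolving the
#' indeterminate component along the stalk with a tension multiplier so that
#' the result is tangent (r_hat . dr_hat/dt = 0).
#'
#' @param state a [tether_state()]
#' @param params a [dynamics_params()]
#' @param ambient an [ambient_flow] (e.g. from [ambient_at()] or
#'   [uniform_flow()])
#' @return dr_hat/dt, a 3-vector (1/s)
#' @export
stalk_rate <- function(state, params, ambient) {
  rhat <- state$stalk_direction
  dhat <- state$cell_orientation
  l <- state$stalk_length
  a <- params$geometry$semi_major
  cf <- params$drag
  mu <- params$fluid$viscosity
  # g = f0 d_hat + 6 pi mu a A u ; solve A^-1 within r_hat x (g - M rdot) = 0
  g <- params$f0 * dhat +
    6 * pi * mu * a * .apply_aniso(ambient$u, dhat, cf$alpha_par, cf$alpha_perp)
  Minv <- function(v) {
    .apply_aniso(v, dhat, 1 / cf$alpha_par, 1 / cf$alpha_perp) /
      (6 * pi * mu * a * l)
  }
  tension <- sum(rhat * Minv(g)) / sum(rhat * Minv(rhat))
  Minv(g - tension * rhat)
}

#' Rate of change of the cell orientation
#'
#' The torque-free reorientation rate of the cell under the ambient
#' velocity, angular velocity and rate of strain.  Exactly tangent to
#' d_hat by construction.
#'
#' @inheritParams stalk_rate
#' @return dd_hat/dt, a 3-vector (1/s)
#' @export
orientation_rate <- function(state, params, ambient) {
  dhat <- state$cell_orientation
  a <- params$geometry$semi_major
  cf <- params$drag
  Au <- .apply_aniso(ambient$u, dhat, cf$alpha_par, cf$alpha_perp)
  BOm <- .apply_aniso(ambient$Omega, dhat, cf$beta_par, cf$beta_perp)
  term <- 3 * cross3(dhat, Au) +
    4 * a * cross3(dhat, BOm) +
    4 * a * cf$beta_perp * cf$gamma * cross3(dhat, as.vector(ambient$E %*% dhat))
  -cross3(dhat, term) / (a * (3 * cf$alpha_perp + 4 * cf$beta_perp))
}

#' Ambient image flow at the tethered cell
#'
#' The image-system flow of the cell's own stokeslet (force -f0 d_hat on the
#' fluid) evaluated at the cell position l r_hat.
#'
#' @inheritParams stalk_rate
#' @return an [ambient_flow]
#' @export
tether_ambient <- function(state, params) {
  pos <- state$stalk_length * state$stalk_direction
  ambient_at(point_force(pos, -params$f0 * state$cell_orientation),
             eval_point = pos, fluid = params$fluid, mode = params$mode)
}

## rates of the full Cartesian state; rhat/dhat defensively renormalized
.tether_rates <- function(rhat, dhat, l, params) {
  rhat <- unitize(rhat)
  dhat <- unitize(dhat)
  st <- structure(list(stalk_direction = rhat, cell_orientation = dhat,
                       stalk_length = l), class = "tether_state")
  amb <- tether_ambient(st, params)
  list(rdot = stalk_rate(st, params, amb),
       ddot = orientation_rate(st, params, amb))
}

#' Reduced planar dynamics
#'
#' By symmetry the motion stays in the vertical plane containing r_hat and
#' d_hat; this evaluates (dtheta/dt, dphi/dt) for in-plane angles, the form
#' in which the phase portrait and the stability analysis are computed.
#'
#' @param theta polar angle of the cell orientation (rad)
#' @param phi polar angle of the stalk (rad), |phi| < pi/2
#' @param params a [dynamics_params()]
#' @param stalk_length stalk length l (um)
#' @return named vector `c(dtheta, dphi)` (1/s)
#' @export
reduced_rates <- function(theta, phi, params, stalk_length) {
  if (abs(cos(phi)) < 1e-6) {
    stop("phi too close to +/- pi/2: the cell is on the wall", call. = FALSE)
  }
  rhat <- c(sin(phi), 0, cos(phi))
  dhat <- c(sin(theta), 0, cos(theta))
  rt <- .tether_rates(rhat, dhat, stalk_length, params)
  c(dtheta = sum(rt$ddot * c(cos(theta), 0, -sin(theta))),
    dphi = sum(rt$rdot * c(cos(phi), 0, -sin(phi))))
}

#' Polar-angle swing rate from the closed-form planar equation
#'
#' The closed-form reduced equation for the cell's polar angle theta under
#' the image flow,
#'   t_f dtheta/dt = ( (9/16) beta_perp a Gamma (3 + cos 2 theta)
#'                     - 3 l alpha_perp cos theta cos phi )
#'                   cos^2(phi) sin(theta) / ( a (3 alpha_perp + 4 beta_perp) ),
#' with t_f = 6 pi mu a l / f0.  The stabilizing term grows with the stalk
#' length l, the destabilizing one with the cell size a.  This closed form
#' involves additional far-field approximations beyond the full 3-D rates;
#' the two agree in sign structure but not prefactor (see the methods
#' vignette), and both are exposed so the discrepancy stays visible.
#'
#' @inheritParams reduced_rates
#' @return dtheta/dt (1/s)
#' @export
polar_rate <- function(theta, phi, params, stalk_length) {
  cf <- params$drag
  a <- params$geometry$semi_major
  t_f <- 6 * pi * params$fluid$viscosity * a * stalk_length / params$f0
  bracket <- (9 / 16) * cf$beta_perp * a * cf$gamma * (3 + cos(2 * theta)) -
    3 * stalk_length * cf$alpha_perp * cos(theta) * cos(phi)
  bracket * cos(phi)^2 * sin(theta) /
    (a * (3 * cf$alpha_perp + 4 * cf$beta_perp)) / t_f
}

#' Characteristic timescales of the tethered cell
#'
#' t_f = 6 pi mu a l / f0 is the fast stalk-alignment (swing) time;
#' t_s = 8 pi mu l^2 / f0 = l / u_s is the slow righting time set by the
#' image back-flow u_s = f0 / (8 pi mu l).  Their ratio is (3/4)(a/l).
#'
#' @param params a [dynamics_params()]
#' @param stalk_length stalk length l (um)
#' @return named vector `c(tau_f, tau_s)` in seconds
#' @examples
#' p <- dynamics_params(cell_geometry(10, 10 / 1.3), 40)
#' timescales(p, 100)   # about 0.47 s and 6.3 s
#' @export
timescales <- function(params, stalk_length) {
  mu <- params$fluid$viscosity
  a <- params$geometry$semi_major
  c(tau_f = 6 * pi * mu * a * stalk_length / params$f0,
    tau_s = 8 * pi * mu * stalk_length^2 / params$f0)
}

#' Critical stalk length
#'
#' The closed-form threshold l_c = 4 beta_perp Gamma a / (3 alpha_perp)
#' below which the upright fixed point loses stability.  Zero for a sphere.
#'
#' @param drag a [drag_coefficients()]
#' @param geometry a [cell_geometry()]
#' @return l_c in the units of the geometry's semi-major axis (um)
#' @examples
#' g <- aspect_geometry(2)
#' critical_length(drag_coefficients(g), g)   # 0.44 a
#' @export
critical_length <- function(drag, geometry) {
  stopifnot(inherits(drag, "drag_coefficients"),
            inherits(geometry, "cell_geometry"))
  4 * drag$beta_perp * drag$gamma * geometry$semi_major / (3 * drag$alpha_perp)
}

#' Linear stability of the upright fixed point
#'
#' Jacobian of the reduced (theta, phi) dynamics at (0, 0) by central finite
#' differences, its eigenvalues, and a classification.  Eigenvalues with
#' |Re lambda| below `marginal_tol / tau_f` are reported as marginal.
#'
#' @param params a [dynamics_params()]
#' @param stalk_length stalk length l (um)
#' @param step finite-difference step (rad)
#' @param marginal_tol dimensionless marginality threshold
#' @return list with `jacobian`, `eigenvalues`, `classification` (one of
#'   `"stable"`, `"unstable"`, `"marginal"`), `stable` (logical)
#' @export
linear_stability <- function(params, stalk_length, step = 1e-5,
                             marginal_tol = 1e-10) {
  J <- matrix(0, 2, 2)
  J[, 1] <- (reduced_rates(step, 0, params, stalk_length) -
               reduced_rates(-step, 0, params, stalk_length)) / (2 * step)
  J[, 2] <- (reduced_rates(0, step, params, stalk_length) -
               reduced_rates(0, -step, params, stalk_length)) / (2 * step)
  ev <- eigen(J, only.values = TRUE)$values
  tau_f <- timescales(params, stalk_length)["tau_f"]
  re <- Re(ev)
  cls <- if (any(abs(re) < marginal_tol / tau_f)) "marginal"
  else if (all(re < 0)) "stable" else "unstable"
  list(jacobian = J, eigenvalues = ev, classification = cls,
       stable = identical(cls, "stable"))
}

#' Numerical critical length by eigenvalue bisection
#'
#' Bisects the leading eigenvalue real part of [linear_stability()] between
#' two stalk lengths.  Because the closed form of [critical_length()] stems
#' from a further-reduced linearization, the two thresholds differ by an
#' order-one factor; both are returned so the discrepancy is explicit.
#'
#' @param params a [dynamics_params()]
#' @param lower,upper bracketing stalk lengths (um); must straddle the
#'   stability change
#' @param iterations bisection iterations
#' @return list with `l_star` (um), `l_c` (closed form, um), `ratio`
#' @export
critical_length_numeric <- function(params, lower, upper, iterations = 40) {
  lead <- function(l) max(Re(linear_stability(params, l)$eigenvalues))
  flo <- lead(lower); fhi <- lead(upper)
  if (sign(flo) == sign(fhi)) {
    stop("bracket does not straddle the stability change", call. = FALSE)
  }
  for (i in seq_len(iterations)) {
    mid <- sqrt(lower * upper)
    if (sign(lead(mid)) == sign(flo)) lower <- mid else upper <- mid
  }
  l_star <- sqrt(lower * upper)
  l_c <- critical_length(params$drag, params$geometry)
  list(l_star = l_star, l_c = l_c, ratio = l_star / l_c)
}

#' Integrate the tethered-cell equations of motion
#'
#' Couples the stalk-swing and cell-reorientation rates, recomputing the
#' image ambient flow from the cell position each step.  Integration is in
#' Cartesian unit vectors with adaptive step control (`deSolve::lsodar`,
#' relative tolerance 1e-8 by default); unit norms are maintained by
#' tangent-space rates plus renormalization inside the derivative.  The run
#' terminates early if the cell descends to the wall (cos phi below
#' `wall_cos`).
#'
#' @param state0 initial [tether_state()]
#' @param params a [dynamics_params()]
#' @param duration total time (s)
#' @param n_out number of output samples
#' @param rtol,atol integrator tolerances
#' @param wall_cos termination threshold on r_hat . e3
#' @return a [tibble::tibble()] with columns `time`, `rx`, `ry`, `rz`,
#'   `dx`, `dy`, `dz`, `theta`, `phi`; attribute `crashed` is TRUE if the
#'   run hit the wall
#' @examples
#' p <- dynamics_params(organism_preset("uronemella")$geometry, 50)
#' s0 <- tether_state(c(sin(0.3), 0, cos(0.3)), c(sin(0.3), 0, cos(0.3)), 125)
#' tr <- integrate_tether(s0, p, duration = 100)
#' tail(tr$theta, 1)   # ~0: the cell has righted itself
#' @export
integrate_tether <- function(state0, params, duration, n_out = 200,
                             rtol = 1e-8, atol = 1e-10, wall_cos = 0.02) {
  stopifnot(inherits(state0, "tether_state"), duration > 0)
  l <- state0$stalk_length
  rhs <- function(t, y, parms) {
    rt <- .tether_rates(y[1:3], y[4:6], l, params)
    list(c(rt$rdot, rt$ddot))
  }
  rootf <- function(t, y, parms) y[3] / vnorm(y[1:3]) - wall_cos
  times <- seq(0, duration, length.out = max(2, n_out))
  y0 <- c(state0$stalk_direction, state0$cell_orientation)
  out <- deSolve::lsodar(y0, times, rhs, parms = NULL, rtol = rtol,
                         atol = atol, rootfunc = rootf)
  crashed <- !is.null(attr(out, "troot")) && length(attr(out, "troot")) > 0
  out <- as.data.frame(out)
  names(out) <- c("time", "rx", "ry", "rz", "dx", "dy", "dz")
  rn <- sqrt(out$rx^2 + out$ry^2 + out$rz^2)
  dn <- sqrt(out$dx^2 + out$dy^2 + out$dz^2)
  res <- tibble::as_tibble(out)
  res$theta <- acos(pmin(1, pmax(-1, out$dz / dn)))
  res$phi <- acos(pmin(1, pmax(-1, out$rz / rn)))
  attr(res, "crashed") <- crashed
  res
}

## refine a fixed point of the reduced dynamics by damped Newton iteration
.refine_fixed_point <- function(theta0, phi0, params, l, step = 1e-6,
                                iterations = 60, tol = 1e-12) {
  x <- c(theta0, phi0)
  for (i in seq_len(iterations)) {
    fx <- reduced_rates(x[1], x[2], params, l)
    if (max(abs(fx)) < tol) break
    J <- matrix(0, 2, 2)
    J[, 1] <- (reduced_rates(x[1] + step, x[2], params, l) -
                 reduced_rates(x[1] - step, x[2], params, l)) / (2 * step)
    J[, 2] <- (reduced_rates(x[1], x[2] + step, params, l) -
                 reduced_rates(x[1], x[2] - step, params, l)) / (2 * step)
    dx <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    dx <- pmin(pmax(-dx, -0.3), 0.3)
    x <- x + dx
    if (abs(x[2]) > pi / 2 - 0.05) return(NULL)
  }
  if (max(abs(reduced_rates(x[1], x[2], params, l))) > 1e-9) return(NULL)
  x
}

#' Phase portrait of the reduced dynamics
#'
#' Evaluates the (theta, phi) vector field on a grid, locates and classifies
#' the fixed points, and (optionally) computes the basin of attraction of
#' the upright fixed point by integrating each grid initial condition until
#' it reaches a fixed point, hits the wall, or exceeds a time cap of
#' `time_cap_tau_s` slow timescales (non-converged points are labelled
#' `"undetermined"`).
#'
#' theta is sampled on [-pi, pi] (its two endpoints describe the same
#' inverted cell and are both reported, as a portrait over the full angular
#' range shows them as two points); phi is restricted to the physical range
#' (-pi/2, pi/2) since beyond it the cell would be below the wall.
#'
#' @param params a [dynamics_params()]
#' @param stalk_length stalk length l (um)
#' @param n_theta,n_phi grid resolution
#' @param basin compute the basin mask (slower)
#' @param phi_margin distance kept from the wall singularity at
#'   |phi| = pi/2 (rad)
#' @param time_cap_tau_s basin time cap in units of tau_s
#' @param converge_tol distance from the upright point counted as converged
#' @return list with `field` (tibble: theta, phi, dtheta, dphi), `fixed_points`
#'   (tibble: theta, phi, eig1, eig2, classification), and if requested
#'   `basin` (tibble: theta, phi, status in attracted/escaped/undetermined)
#' @export
phase_portrait <- function(params, stalk_length, n_theta = 25, n_phi = 13,
                           basin = FALSE, phi_margin = 0.12,
                           time_cap_tau_s = 200, converge_tol = 1e-3) {
  thetas <- seq(-pi, pi, length.out = n_theta)
  phis <- seq(-pi / 2 + phi_margin, pi / 2 - phi_margin, length.out = n_phi)
  grid <- expand.grid(theta = thetas, phi = phis)
  rates <- t(mapply(function(th, ph) reduced_rates(th, ph, params, stalk_length),
                    grid$theta, grid$phi))
  field <- tibble::tibble(theta = grid$theta, phi = grid$phi,
                          dtheta = rates[, 1], dphi = rates[, 2])

  # fixed-point candidates: local minima of the field magnitude, refined
  mag <- sqrt(rates[, 1]^2 + rates[, 2]^2)
  cand <- grid[mag < stats::quantile(mag, 0.2), , drop = FALSE]
  found <- list()
  for (i in seq_len(nrow(cand))) {
    fp <- .refine_fixed_point(cand$theta[i], cand$phi[i], params, stalk_length)
    if (is.null(fp)) next
    # snap theta to [-pi, pi]
    fp[1] <- atan2(sin(fp[1]), cos(fp[1]))
    dup <- any(vapply(found, function(g) {
      max(abs(atan2(sin(g - fp), cos(g - fp)))) < 1e-3
    }, logical(1)))
    if (!dup) found[[length(found) + 1]] <- fp
  }
  # report both +/- pi representations of an inverted-cell fixed point,
  # matching a portrait drawn over the closed theta range
  wrapped <- list()
  for (fp in found) {
    wrapped[[length(wrapped) + 1]] <- fp
    if (abs(abs(fp[1]) - pi) < 1e-6) {
      wrapped[[length(wrapped) + 1]] <- c(-fp[1], fp[2])
    }
  }
  classify <- function(fp) {
    step <- 1e-5
    J <- matrix(0, 2, 2)
    J[, 1] <- (reduced_rates(fp[1] + step, fp[2], params, stalk_length) -
                 reduced_rates(fp[1] - step, fp[2], params, stalk_length)) / (2 * step)
    J[, 2] <- (reduced_rates(fp[1], fp[2] + step, params, stalk_length) -
                 reduced_rates(fp[1], fp[2] - step, params, stalk_length)) / (2 * step)
    eigen(J, only.values = TRUE)$values
  }
  fps <- lapply(wrapped, function(fp) {
    ev <- classify(fp)
    re <- Re(ev)
    cls <- if (all(re < 0)) "stable"
    else if (all(re > 0)) "unstable"
    else "saddle"
    tibble::tibble(theta = fp[1], phi = fp[2],
                   eig1 = ev[1], eig2 = ev[2], classification = cls)
  })
  fps <- if (length(fps)) do.call(rbind, fps) else
    tibble::tibble(theta = numeric(), phi = numeric(), eig1 = complex(),
                   eig2 = complex(), classification = character())
  out <- list(field = field, fixed_points = fps)

  if (basin) {
    tau_s <- timescales(params, stalk_length)["tau_s"]
    status <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      status[i] <- .basin_status(grid$theta[i], grid$phi[i], params,
                                 stalk_length, time_cap_tau_s * tau_s,
                                 converge_tol)
    }
    out$basin <- tibble::tibble(theta = grid$theta, phi = grid$phi,
                                status = status)
  }
  out
}

#' Basin membership of a single initial condition
#'
#' Integrates from planar angles (theta0, phi0) and reports whether the
#' trajectory reaches the upright fixed point (`"attracted"`), hits the wall
#' or parks at another fixed point (`"escaped"`), or fails to settle within
#' the time cap (`"undetermined"`).
#'
#' @param theta0,phi0 initial planar angles (rad)
#' @param params a [dynamics_params()]
#' @param stalk_length stalk length (um)
#' @param time_cap integration cap (s)
#' @param tol convergence tolerance on (theta, phi)
#' @return character status
#' @export
basin_status <- function(theta0, phi0, params, stalk_length,
                         time_cap = NULL, tol = 1e-3) {
  if (is.null(time_cap)) {
    time_cap <- 200 * timescales(params, stalk_length)["tau_s"]
  }
  .basin_status(theta0, phi0, params, stalk_length, time_cap, tol)
}

.basin_status <- function(theta0, phi0, params, l, time_cap, tol) {
  s0 <- tryCatch(
    tether_state(c(sin(phi0), 0, cos(phi0)), c(sin(theta0), 0, cos(theta0)), l),
    error = function(e) NULL)
  if (is.null(s0)) return("escaped")
  # integrate in chunks so easy cases exit early
  chunks <- 8
  state <- s0
  for (k in seq_len(chunks)) {
    tr <- integrate_tether(state, params, duration = time_cap / chunks,
                           n_out = 25)
    fin <- tr[nrow(tr), ]
    if (isTRUE(attr(tr, "crashed"))) return("escaped")
    if (sqrt(fin$theta^2 + fin$phi^2) < tol) return("attracted")
    # parked at the inverted fixed point
    if (abs(fin$theta - pi) < tol && abs(fin$phi) < tol) return("escaped")
    state <- tether_state(unitize(c(fin$rx, fin$ry, fin$rz)),
                          unitize(c(fin$dx, fin$dy, fin$dz)), l)
  }
  "undetermined"
}
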