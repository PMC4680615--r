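# Two-dimensional observation-chamber model: oxygen diffuses in from the
# gas-permeable edges (Dirichlet boundary), is consumed where cells sit, and
# the cells are chemotactic random walkers biased toward their preferred
# concentration c*.  Starting from a uniform suspension, consumption
# depletes the interior and the walkers collapse onto the ring where the
# concentration crosses c* - a dense front at a fixed oxygen level.  For
# each stored state the model also renders a Stern-Volmer fluorescence image
# of the oxygen field and a frame PAIR of scattered-light cell images, so
# the frame-differencing measurement stage can be exercised.
#
# Units here are cm, s, % of atmospheric oxygen saturation.

#' Chamber configuration
#'
#' @param n grid size (n x n pixels)
#' @param side chamber side length (cm)
#' @param diffusivity oxygen diffusivity (cm^2/s)
#' @param boundary_conc oxygen at the chamber edges (% atm)
#' @param consumption per-cell oxygen consumption (% atm cm^2 / s), removed
#'   each step from the cell's neighbourhood
#' @param consumption_spread half-width (pixels) of the square neighbourhood
#'   over which a cell's consumption is deposited; swimming cells roam
#'   several pixels between steps, so point deposition would carve an
#'   unphysical pit under each walker
#' @param n_cells number of walkers
#' @param motility random-walk scale (cm per sqrt(s)); per-step displacement
#'   sd is `motility * sqrt(dt)` per axis
#' @param preferred_conc chemotactic preference c* (% atm), in (0, 100)
#' @param chemotactic_strength drift speed per unit concentration error
#'   (cm/s per % atm); the drift is `-strength * (c - c*)` along the unit
#'   gradient, capped at `max_drift`
#' @param max_drift drift speed cap (cm/s)
#' @param gradient_stencil half-width (pixels) of the finite-difference
#'   stencil for the gradient the cells sense; wider than one pixel so a
#'   cell's own consumption pit does not dominate its steering
#' @param I0,K_sv Stern-Volmer constants of the rendered fluorescence image
#' @param dt time step (s); must satisfy the explicit-diffusion stability
#'   bound D dt / dx^2 <= 0.25
#' @param pair_lag number of steps between the two frames of each stored
#'   frame pair (so cells move appreciably between them, as with paired
#'   photos taken seconds apart)
#' @param imaging_jitter sd (cm) of the apparent per-snapshot displacement
#'   of each cell: the cells swim hundreds of um between any two photos, so
#'   sequential frames show every cell at a decorrelated position around its
#'   slowly drifting mean
#' @param seed integer seed
#' @return an object of class `chamber_config`
#' @examples
#' chamber_config(n = 32, n_cells = 20)
#' @export
chamber_config <- function(n = 128, side = 1.5, diffusivity = 1e-5,
                           boundary_conc = 100, consumption = 1e-4,
                           consumption_spread = 2, n_cells = 300, motility = 2e-3,
                           preferred_conc = 7, chemotactic_strength = 5e-4,
                           max_drift = 3e-3, gradient_stencil = 3,
                           I0 = 1, K_sv = 0.01, dt = 2, pair_lag = 10,
                           imaging_jitter = 0.008, seed = 1) {
  stopifnot(n >= 8, side > 0, diffusivity > 0, boundary_conc > 0,
            consumption >= 0, n_cells >= 0, motility >= 0,
            preferred_conc > 0, preferred_conc < 100,
            chemotactic_strength >= 0, dt > 0)
  dx <- side / n
  if (diffusivity * dt / dx^2 > 0.25) {
    stop(sprintf(
      "explicit-diffusion stability violated: D*dt/dx^2 = %.3g > 0.25",
      diffusivity * dt / dx^2), call. = FALSE)
  }
  structure(
    list(n = n, side = side, dx = dx, diffusivity = diffusivity,
         boundary_conc = boundary_conc, consumption = consumption,
         consumption_spread = consumption_spread,
         n_cells = n_cells, motility = motility,
         preferred_conc = preferred_conc,
         chemotactic_strength = chemotactic_strength,
         max_drift = max_drift, gradient_stencil = gradient_stencil,
         I0 = I0, K_sv = K_sv, dt = dt, pair_lag = pair_lag,
         imaging_jitter = imaging_jitter, seed = seed),
    class = "chamber_config"
  )
}

## render a scattered-light image: one unit of intensity per cell pixel.
## Each snapshot sees the cell displaced by its fast swimming motion
## (imaging_jitter, in cm), which decorrelates sequential frames for every
## cell - the cells swim at hundreds of um/s, far faster than their net
## chemotactic drift, so any two photos seconds apart show them at
## independently jittered positions.
.render_cells <- function(pos, cfg) {
  img <- matrix(0, cfg$n, cfg$n)
  if (nrow(pos) == 0) return(img)
  jit <- matrix(stats::rnorm(length(pos), 0, cfg$imaging_jitter), ncol = 2)
  shown <- pos + jit
  shown[shown < 0] <- -shown[shown < 0]
  shown[shown > cfg$side] <- 2 * cfg$side - shown[shown > cfg$side]
  ij <- .cell_pixels(shown, cfg)
  for (k in seq_len(nrow(ij))) img[ij[k, 1], ij[k, 2]] <- img[ij[k, 1], ij[k, 2]] + 1
  img
}

.cell_pixels <- function(pos, cfg) {
  cbind(pmin(pmax(floor(pos[, 1] / cfg$dx) + 1L, 1L), cfg$n),
        pmin(pmax(floor(pos[, 2] / cfg$dx) + 1L, 1L), cfg$n))
}

#' Simulate the chemotactic chamber
#'
#' Explicit time stepping of the oxygen field (five-point Laplacian,
#' Dirichlet edges) coupled to chemotactic random walkers that consume
#' oxygen at their pixel.  States are stored every `stride` seconds; each
#' stored state carries the oxygen field, cell positions, a Stern-Volmer
#' fluorescence image, and a frame pair of scattered-light cell images (the
#' current frame and the frame one step earlier) for frame differencing.
#' Deterministic for a given config (the seed lives in the config).
#'
#' @param config a [chamber_config()]
#' @param duration simulated time (s)
#' @param stride interval between stored states (s)
#' @return list of `chamber_state` objects, each a list with `time`,
#'   `oxygen` (matrix, % atm), `cells` (n_cells x 2, cm), `fluorescence`,
#'   `cell_image`, `prev_cell_image`; the list carries attributes `config`
#'   and `seed`
#' @examples
#' cfg <- chamber_config(n = 32, n_cells = 30, dt = 1)
#' states <- simulate_chamber(cfg, duration = 200, stride = 100)
#' @export
simulate_chamber <- function(config, duration = 5000, stride = 500) {
  stopifnot(inherits(config, "chamber_config"), duration > 0,
            stride >= config$dt)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n
  cb <- cfg$boundary_conc
  conc <- matrix(cb, n, n)
  pos <- matrix(stats::runif(2 * cfg$n_cells, 0, cfg$side), ncol = 2)
  n_steps <- ceiling(duration / cfg$dt)
  store_every <- max(1L, round(stride / cfg$dt))
  pair_lag <- min(cfg$pair_lag, store_every)
  states <- list()
  prev_img <- .render_cells(pos, cfg)
  dx <- cfg$dx
  cons <- cfg$consumption * cfg$dt / dx^2
  st <- cfg$gradient_stencil
  for (s in seq_len(n_steps)) {
    lap <- (rbind(conc[-1, ], cb) + rbind(cb, conc[-n, ]) +
              cbind(conc[, -1], cb) + cbind(cb, conc[, -n]) - 4 * conc) / dx^2
    conc <- conc + cfg$dt * cfg$diffusivity * lap
    conc[1, ] <- cb; conc[n, ] <- cb; conc[, 1] <- cb; conc[, n] <- cb
    if (cfg$n_cells > 0) {
      ij <- .cell_pixels(pos, cfg)
      w <- cfg$consumption_spread
      for (k in seq_len(nrow(ij))) {
        ii <- max(1L, ij[k, 1] - w):min(n, ij[k, 1] + w)
        jj <- max(1L, ij[k, 2] - w):min(n, ij[k, 2] + w)
        conc[ii, jj] <- conc[ii, jj] - cons / (length(ii) * length(jj))
      }
      conc[conc < 0] <- 0
      ip <- pmin(ij[, 1] + st, n); im <- pmax(ij[, 1] - st, 1L)
      jp <- pmin(ij[, 2] + st, n); jm <- pmax(ij[, 2] - st, 1L)
      gx <- (conc[cbind(ip, ij[, 2])] - conc[cbind(im, ij[, 2])]) / ((ip - im) * dx)
      gy <- (conc[cbind(ij[, 1], jp)] - conc[cbind(ij[, 1], jm)]) / ((jp - jm) * dx)
      gn <- sqrt(gx^2 + gy^2) + 1e-9
      cc <- conc[ij]
      drift <- -cfg$chemotactic_strength * (cc - cfg$preferred_conc)
      drift <- sign(drift) * pmin(abs(drift), cfg$max_drift)
      step_sd <- cfg$motility * sqrt(cfg$dt)
      pos[, 1] <- pos[, 1] + cfg$dt * drift * gx / gn +
        stats::rnorm(cfg$n_cells, 0, step_sd)
      pos[, 2] <- pos[, 2] + cfg$dt * drift * gy / gn +
        stats::rnorm(cfg$n_cells, 0, step_sd)
      # reflecting walls
      pos[pos < 0] <- -pos[pos < 0]
      pos[pos > cfg$side] <- 2 * cfg$side - pos[pos > cfg$side]
    }
    if (s %% store_every == 0 || s == n_steps) {
      img <- .render_cells(pos, cfg)
      states[[length(states) + 1]] <- structure(
        list(time = s * cfg$dt,
             oxygen = conc,
             cells = pos,
             fluorescence = stern_volmer_image(conc, cfg$I0, cfg$K_sv),
             cell_image = img,
             prev_cell_image = prev_img),
        class = "chamber_state")
      prev_img <- img
    } else if (s %% store_every == store_every - pair_lag) {
      prev_img <- .render_cells(pos, cfg)
    }
  }
  attr(states, "config") <- cfg
  attr(states, "seed") <- cfg$seed
  states
}
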