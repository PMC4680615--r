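# Synthetic-data generators emulating the bench observations: displacement
# tracks of anchored cells whose stalks elongate linearly, scattered-light
# series from accumulating veil material, and Stern-Volmer fluorescence
# images of an oxygen field.  Every generator takes an explicit seed and
# records it in an attribute, so downstream measurement stages can be tested
# end-to-end without any external data.

#' Synthetic stalk-elongation tracks
#'
#' Positions of anchored cells drifting away from their anchor as the stalk
#' elongates at a constant rate: displacement(t) = rate * t plus isotropic
#' Gaussian localization noise.  Each track is launched in a random
#' direction from a random origin.
#'
#' @param rate elongation rate (um/s)
#' @param n_tracks number of cells
#' @param duration track length (s)
#' @param dt sampling interval (s)
#' @param noise_sd localization noise per coordinate (um)
#' @param seed integer seed
#' @return a [tibble::tibble()] with columns `track_id`, `time` (s), `x`,
#'   `y` (um); attribute `seed` carries the seed
#' @examples
#' tr <- generate_stalk_tracks(0.65, n_tracks = 3, duration = 30, dt = 1)
#' @export
generate_stalk_tracks <- function(rate, n_tracks = 10, duration = 30, dt = 1,
                                  noise_sd = 0.3, seed = 1) {
  stopifnot(rate >= 0, dt > 0, n_tracks >= 1)
  if (duration < dt) stop("duration must be at least one sampling interval",
                          call. = FALSE)
  set.seed(seed)
  times <- seq(0, duration, by = dt)
  out <- vector("list", n_tracks)
  for (k in seq_len(n_tracks)) {
    ang <- stats::runif(1, 0, 2 * pi)
    origin <- stats::runif(2, 0, 500)
    disp <- rate * times
    out[[k]] <- tibble::tibble(
      track_id = k,
      time = times,
      x = origin[1] + disp * cos(ang) + stats::rnorm(length(times), 0, noise_sd),
      y = origin[2] + disp * sin(ang) + stats::rnorm(length(times), 0, noise_sd)
    )
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- seed
  attr(res, "rate") <- rate
  res
}

#' Stern-Volmer fluorescence image of an oxygen field
#'
#' Pointwise quenching I = I0 / (1 + K_sv * c): fluorescence is maximal at
#' zero oxygen and falls hyperbolically with concentration.
#'
#' @param oxygen matrix of concentrations (% atm), >= 0
#' @param I0 intensity at zero oxygen
#' @param K_sv Stern-Volmer constant (per % atm)
#' @return intensity matrix of the same shape
#' @examples
#' stern_volmer_image(matrix(c(0, 100), 1), I0 = 1, K_sv = 0.01)
#' @export
stern_volmer_image <- function(oxygen, I0 = 1, K_sv = 0.01) {
  stopifnot(is.numeric(oxygen), all(oxygen >= 0), I0 > 0, K_sv > 0)
  I0 / (1 + K_sv * oxygen)
}

#' Synthetic veil scattered-light series
#'
#' Veil material accumulates at a rate proportional to the instantaneous
#' cell count, so the scattered intensity tracks the running time-integral
#' of the count (the integrated cell number, computed by the trapezoid
#' rule), plus optional Gaussian noise.
#'
#' @param times sample times (s), strictly increasing
#' @param cell_count cell count at each time (>= 0)
#' @param production_rate intensity produced per cell-second (a.u.)
#' @param intensity_noise_sd additive noise on the intensity (a.u.)
#' @param seed integer seed
#' @return a [tibble::tibble()] with columns `time`, `cell_count`,
#'   `integrated_cell_number` (cell-seconds), `scattered_intensity` (a.u.)
#' @examples
#' generate_veil_series(0:100, rep(200, 101), production_rate = 0.01)
#' @export
generate_veil_series <- function(times, cell_count, production_rate,
                                 intensity_noise_sd = 0, seed = 1) {
  stopifnot(length(times) == length(cell_count), all(diff(times) > 0),
            all(cell_count >= 0), production_rate >= 0)
  set.seed(seed)
  n <- length(times)
  icn <- c(0, cumsum(diff(times) * (cell_count[-1] + cell_count[-n]) / 2))
  intensity <- production_rate * icn
  if (intensity_noise_sd > 0) {
    intensity <- intensity + stats::rnorm(n, 0, intensity_noise_sd)
  }
  res <- tibble::tibble(time = times, cell_count = cell_count,
                        integrated_cell_number = icn,
                        scattered_intensity = intensity)
  attr(res, "seed") <- seed
  res
}
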