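# Measurement stages mirroring the bench procedures: per-cell line fits of
# displacement for the stalk elongation rate; two-point Stern-Volmer
# calibration and pointwise inversion of fluorescence to oxygen; frame
# differencing to localize moving cells; front detection with a cross-front
# profile; and the linear fit of scattered-light intensity against the
# integrated cell number.  Every stage is a pure function of its inputs.

#' Fit the stalk elongation rate from displacement tracks
#'
#' For each track the displacement from its first point is projected onto
#' the track's principal displacement axis (the stand-in for the stalk
#' direction when only point positions are available) and regressed against
#' time by ordinary least squares.  The aggregate rate is the unweighted
#' mean of the per-track slopes; its standard error is computed across
#' tracks.
#'
#' @param tracks a track table with columns `track_id`, `time`, `x`, `y`
#' @return list with `rate` (um/s), `se`, `n_tracks`, and `per_track`
#'   (tibble of per-track slopes)
#' @examples
#' tr <- generate_stalk_tracks(0.65, n_tracks = 5, noise_sd = 0)
#' fit_elongation_rate(tr)$rate   # 0.65 exactly
#' @export
fit_elongation_rate <- function(tracks) {
  stopifnot(all(c("track_id", "time", "x", "y") %in% names(tracks)))
  ids <- unique(tracks$track_id)
  if (length(ids) < 1) stop("no tracks", call. = FALSE)
  slopes <- vapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < 3) stop("each track needs at least 3 points", call. = FALSE)
    if (diff(range(tr$time)) == 0) {
      stop("degenerate track: constant time", call. = FALSE)
    }
    xy <- cbind(tr$x - tr$x[1], tr$y - tr$y[1])
    # principal displacement axis from the second moment of the displacements
    sv <- svd(xy)
    axis <- sv$v[, 1]
    disp <- xy %*% axis
    # orient the axis along the motion so the slope is positive for growth
    if (stats::cor(as.numeric(disp), tr$time) < 0) disp <- -disp
    unname(stats::coef(stats::lm(disp ~ tr$time))[2])
  }, numeric(1))
  se <- if (length(slopes) > 1) stats::sd(slopes) / sqrt(length(slopes)) else NA_real_
  list(rate = mean(slopes), se = se, n_tracks = length(ids),
       per_track = tibble::tibble(track_id = ids, slope = slopes))
}

#' Two-point Stern-Volmer calibration
#'
#' Solves I = I0 / (1 + K_sv c) through the two anchor measurements at
#' c = 0 and c = 100 % atm.
#'
#' @param intensity_zero intensity at zero oxygen
#' @param intensity_sat intensity at 100 % atmospheric saturation; must be
#'   smaller than `intensity_zero` (oxygen quenches)
#' @return an object of class `sv_calibration`: list with `I0`, `K_sv`
#' @examples
#' calibrate(1.0, 0.5)   # I0 = 1, K_sv = 0.01 per % atm
#' @export
calibrate <- function(intensity_zero, intensity_sat) {
  stopifnot(intensity_zero > 0, intensity_sat > 0)
  if (intensity_sat >= intensity_zero) {
    stop("no quenching: saturated intensity must be below zero-oxygen intensity",
         call. = FALSE)
  }
  K_sv <- (intensity_zero / intensity_sat - 1) / 100
  structure(list(I0 = intensity_zero, K_sv = K_sv), class = "sv_calibration")
}

#' Invert a fluorescence image to an oxygen map
#'
#' Normalizes the image by a reference frame taken at full saturation (which
#' cancels any spatial variation in dye loading), then inverts the
#' Stern-Volmer relation pointwise.
#'
#' @param fluorescence intensity matrix
#' @param calibration an [calibrate()] result
#' @param reference intensity matrix at 100 % saturation, strictly positive;
#'   defaults to the uniform saturated intensity implied by the calibration
#' @return oxygen matrix (% atm)
#' @examples
#' cal <- calibrate(1, 0.5)
#' oxy <- matrix(c(0, 7, 50, 100), 2)
#' img <- stern_volmer_image(oxy, cal$I0, cal$K_sv)
#' oxygen_map(img, cal)   # recovers oxy
#' @export
oxygen_map <- function(fluorescence, calibration, reference = NULL) {
  stopifnot(inherits(calibration, "sv_calibration"))
  I0 <- calibration$I0
  K <- calibration$K_sv
  if (is.null(reference)) {
    reference <- matrix(I0 / (1 + 100 * K), nrow(fluorescence), ncol(fluorescence))
  }
  if (any(reference <= 0) || any(fluorescence <= 0)) {
    stop("intensities must be strictly positive", call. = FALSE)
  }
  if (!all(dim(fluorescence) == dim(reference))) {
    stop("image and reference shapes differ", call. = FALSE)
  }
  # I/I_ref = (1 + 100 K) / (1 + K c)  =>  c = ((1 + 100 K) I_ref/I - 1)/K
  ratio <- fluorescence / reference
  ((1 + 100 * K) / ratio - 1) / K
}

## separable Gaussian smoothing with renormalized (zero-padded) edges
.gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  smooth1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- matrix(0, n, ncol(m))
    for (o in seq(-half, half)) {
      w <- kern[o + half + 1]
      src <- seq_len(n) + o
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + w * m[src[ok], ]
      wt[ok, ] <- wt[ok, ] + w
    }
    out / wt
  }
  t(smooth1(t(smooth1(img))))
}

#' Cell-density map by frame differencing
#'
#' Approximates the time derivative of the scattered-light image by the
#' difference of two sequential frames: fast-moving cells light up where
#' they are, while static background cancels.  The absolute difference is
#' Gaussian-smoothed into a density map.
#'
#' @param frame,prev_frame equal-shape intensity matrices
#' @param sigma smoothing scale (pixels)
#' @return nonnegative density matrix
#' @export
cell_density_map <- function(frame, prev_frame, sigma = 1) {
  if (!all(dim(frame) == dim(prev_frame))) {
    stop("frame shapes differ", call. = FALSE)
  }
  .gaussian_blur(abs(frame - prev_frame), sigma)
}

#' Detect the cell front and the oxygen level it sits at
#'
#' Front pixels are those whose (smoothed) density exceeds a high quantile
#' of the density distribution; the front concentration is the
#' median oxygen over those pixels (median rather than mean, to resist
#' outliers at the band ends).  Also returns the cross-front profile:
#' density and oxygen averaged in bins of signed distance to the nearest
#' front pixel, signed negative on the oxygen-poor side.
#'
#' @param density density matrix (e.g. from [cell_density_map()])
#' @param oxygen oxygen matrix (% atm), same shape
#' @param quantile_threshold density quantile defining the front
#' @param profile_halfwidth half-width of the profile (pixels)
#' @return list with `front_pixels` (two-column matrix of indices),
#'   `front_concentration` (% atm), `profile` (tibble: distance_px,
#'   density, oxygen)
#' @export
front_report <- function(density, oxygen, quantile_threshold = 0.99,
                         profile_halfwidth = 15) {
  if (!all(dim(density) == dim(oxygen))) {
    stop("density and oxygen shapes differ", call. = FALSE)
  }
  if (stats::sd(as.vector(density)) == 0) {
    stop("no front: density is uniform", call. = FALSE)
  }
  thr <- stats::quantile(density, quantile_threshold)
  idx <- which(density >= thr & density > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no front: threshold too high", call. = FALSE)
  front_conc <- stats::median(oxygen[idx])

  # signed distance of every pixel to the nearest front pixel (brute force
  # on a subsample of front pixels for speed), negative on the low-oxygen side
  sub <- idx[seq(1, nrow(idx), length.out = min(200, nrow(idx))), , drop = FALSE]
  nr <- nrow(density); nc <- ncol(density)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dmin <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(sub))) {
    dk <- sqrt((rows - sub[k, 1])^2 + (cols - sub[k, 2])^2)
    dmin <- pmin(dmin, dk)
  }
  signed <- ifelse(oxygen < front_conc, -dmin, dmin)
  keep <- abs(signed) <= profile_halfwidth
  bins <- round(signed[keep])
  prof <- tibble::tibble(
    distance_px = sort(unique(bins)),
    density = as.numeric(tapply(density[keep], bins, mean)),
    oxygen = as.numeric(tapply(oxygen[keep], bins, mean))
  )
  list(front_pixels = idx, front_concentration = unname(front_conc),
       profile = prof)
}

#' Fit veil production against the integrated cell number
#'
#' Ordinary least squares of the scattered-intensity change against the
#' integrated cell number, with R^2 as the linearity diagnostic.  A slope
#' close to the generating production rate and R^2 near 1 confirm that veil
#' material accumulates in proportion to cell-seconds.
#'
#' @param series a veil series with columns `integrated_cell_number` and
#'   `scattered_intensity` (e.g. from [generate_veil_series()])
#' @return list with `slope` (a.u. per cell-second), `intercept`,
#'   `r_squared`
#' @export
veil_production_fit <- function(series) {
  stopifnot(all(c("integrated_cell_number", "scattered_intensity") %in%
                  names(series)))
  if (nrow(series) < 3) stop("need at least 3 rows", call. = FALSE)
  x <- series$integrated_cell_number
  if (stats::sd(x) == 0) stop("constant regressor", call. = FALSE)
  fit <- stats::lm(scattered_intensity ~ integrated_cell_number, data = series)
  y <- series$scattered_intensity
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}
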