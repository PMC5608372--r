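#' Synthetic oxygen-sensor intensity map
#'
#' Emulates a fluorescence image of the device oxygen field: per-pixel
#' intensity follows the Stern-Volmer relation applied to the device profile
#' at the pixel's position, with multiplicative Gaussian noise.  Inverting
#' the map through [intensityToOxygen()] and smoothing with a 20-point
#' rolling average recovers the profile.
#'
#' @param profile a [DeviceProfile-class]
#' @param cal a [CalibrationCurve-class]
#' @param nx,ny image dimensions (columns along the gradient, rows repeat it)
#' @param xRange positions (um from the wall centre) spanned by the columns
#' @param height sensor height above the membrane (um)
#' @param noiseSd multiplicative noise sigma (fraction of intensity)
#' @param seed optional RNG seed
#' @return list with \code{x} (column positions, um), \code{intensity}
#'   (ny x nx matrix) and \code{height}
#' @export
genSensorMap <- function(profile, cal, nx = 400, ny = 20,
                         xRange = c(-1000, 1000), height = 0,
                         noiseSd = 0.01, seed = NULL) {
  stopifnot(is(profile, "DeviceProfile"), is(cal, "CalibrationCurve"))
  if (!is.null(seed)) set.seed(seed)
  x <- seq(xRange[1], xRange[2], length.out = nx)
  conc <- deviceOxygenAt(x, height, profile)
  base <- oxygenToIntensity(conc, cal)
  img <- matrix(rep(base, each = ny), nrow = ny)
  if (noiseSd > 0)
    img <- img * (1 + matrix(rnorm(nx * ny, 0, noiseSd), nrow = ny))
  list(x = x, intensity = img, height = height)
}

#' Synthetic pole-cell trajectory
#'
#' Generates a logistic position profile from 0.05 to 0.5 EL whose analytic
#' 10-90\% crossing interval equals the migration duration implied by the
#' dose-response curve at the given oxygen level (or an explicit
#' \code{targetDuration}).  Oxygen at or below the curve's asymptote yields
#' an arrested (flat) trajectory spanning the watch window.
#'
#' @param o2 oxygen concentration (\% O2) at the embryo
#' @param fit a [DoseResponseFit-class]
#' @param frameInterval imaging interval (min)
#' @param noiseSd additive positional noise sigma (EL)
#' @param watch watch window for arrested tracks (min)
#' @param targetDuration override the curve-implied 10-90 duration (min)
#' @param seed optional RNG seed
#' @return a [Trajectory-class]
#' @export
genTrajectory <- function(o2, fit, frameInterval = 3, noiseSd = 0,
                          watch = 500, targetDuration = NULL, seed = NULL) {
  stopifnot(is(fit, "DoseResponseFit"))
  if (!is.null(seed)) set.seed(seed)
  arrested <- is.null(targetDuration) && o2 <= fit@a
  if (arrested) {
    times <- seq(0, watch, by = frameInterval)
    pos <- rep(0.05, length(times))
  } else {
    Tm <- if (is.null(targetDuration)) invertDoseResponse(fit, o2)
          else targetDuration
    k <- 2 * log(9) / Tm        # logistic 10-90 interval is 2 ln(9) / k
    # centre the transition well inside the window so the observed span is
    # effectively the full 0.45 EL and the 10/90 thresholds are unbiased
    t0 <- 2 * Tm
    times <- seq(0, 4 * Tm, by = frameInterval)
    pos <- 0.05 + 0.45 / (1 + exp(-k * (times - t0)))
  }
  if (noiseSd > 0)
    pos <- pmin(pmax(pos + rnorm(length(pos), 0, noiseSd), 0), 1)
  trajectory(times, pos)
}

#' Synthetic migration-time dataset
#'
#' Draws oxygen levels uniformly over a range, maps each to a stripe
#' migration time through the inverse dose-response curve, and adds Gaussian
#' observation noise to the recorded oxygen.  Levels at or below the curve's
#' asymptote (and times exceeding the watch window) are right-censored at
#' the watch time.
#'
#' @param n number of observations (>= 4)
#' @param fit a [DoseResponseFit-class]
#' @param o2Range range (\% O2) to sample uniformly
#' @param noiseSd Gaussian sigma added to the recorded oxygen (\% O2)
#' @param watch censoring watch time (min)
#' @param seed optional RNG seed
#' @return data.frame with columns \code{t_min}, \code{o2_percent},
#'   \code{censored}
#' @export
genMigrationDataset <- function(n, fit, o2Range = c(5.5, 20),
                                noiseSd = 0.5, watch = 500, seed = NULL) {
  stopifnot(is(fit, "DoseResponseFit"), n >= 4)
  if (!is.null(seed)) set.seed(seed)
  o2_true <- runif(n, o2Range[1], o2Range[2])
  t <- rep(watch, n)
  censored <- o2_true <= fit@a
  if (any(!censored))
    t[!censored] <- invertDoseResponse(fit, o2_true[!censored])
  over <- t >= watch
  censored <- censored | over
  t[censored] <- watch
  o2_obs <- o2_true + if (noiseSd > 0) rnorm(n, 0, noiseSd) else 0
  data.frame(t_min = t, o2_percent = o2_obs, censored = censored)
}

#' Synthetic engrailed stripe passage records
#'
#' Emits passage times of the 14 stripes at the posterior reference point,
#' spaced so that every adjacent interval -- in particular the 10th-to-11th
#' -- equals the migration time implied by the dose-response curve at the
#' given oxygen level.  In the arrested regime (oxygen at or below the
#' asymptote) only the stripes that passed before the arrest are recorded,
#' so the 10th and 11th passages are absent.
#'
#' @param o2 oxygen concentration (\% O2)
#' @param fit a [DoseResponseFit-class]
#' @param start passage time of the first stripe (min)
#' @param noiseSd Gaussian sigma on passage times (min)
#' @param preArrestInterval spacing (min) used for the stripes recorded
#'   before an arrest
#' @param seed optional RNG seed
#' @return data.frame with columns \code{stripe_index}, \code{t_min}
#' @export
genStripePassages <- function(o2, fit, start = 0, noiseSd = 0,
                              preArrestInterval = 22, seed = NULL) {
  stopifnot(is(fit, "DoseResponseFit"))
  if (!is.null(seed)) set.seed(seed)
  if (o2 <= fit@a) {
    idx <- 1:9
    t <- start + (idx - 1) * preArrestInterval
  } else {
    interval <- invertDoseResponse(fit, o2)
    idx <- 1:14
    t <- start + (idx - 1) * interval
  }
  if (noiseSd > 0) t <- t + rnorm(length(t), 0, noiseSd)
  data.frame(stripe_index = idx, t_min = t)
}
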