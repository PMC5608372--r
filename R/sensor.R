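#' Calibrate a Stern-Volmer oxygen sensor
#'
#' Fits the quenching relation \eqn{I_0/I = 1 + K_{sv} C} to intensities
#' recorded at known oxygen concentrations.  \code{I0} is taken as the mean
#' intensity at C = 0 (so the line's intercept is 1 by construction) and
#' \code{Ksv} as the ordinary least-squares slope of \eqn{I_0/I - 1} on C
#' through the origin.
#'
#' @param concentrations known oxygen concentrations (\% O2); must contain 0
#'   and at least one other distinct level
#' @param intensities measured intensities (arbitrary units), all > 0,
#'   matched to \code{concentrations}
#' @return a [CalibrationCurve-class]
#' @examples
#' cal <- calibrationCurve(I0 = 1000, Ksv = 0.05)
#' C <- c(0, 10, 21)
#' fitSternVolmer(C, oxygenToIntensity(C, cal))
#' @export
fitSternVolmer <- function(concentrations, intensities) {
  concentrations <- as.numeric(concentrations)
  intensities <- as.numeric(intensities)
  if (length(concentrations) != length(intensities))
    stop("concentrations and intensities must have equal length")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("all intensities must be positive")
  if (length(unique(concentrations)) < 2L)
    stop("invalid calibration: need at least 2 distinct concentrations")
  if (!any(concentrations == 0))
    stop("invalid calibration: a zero-oxygen reference is required")
  I0 <- mean(intensities[concentrations == 0])
  nz <- concentrations != 0
  y <- I0 / intensities[nz] - 1
  x <- concentrations[nz]
  Ksv <- sum(x * y) / sum(x * x)   # OLS through the origin
  if (!is.finite(Ksv) || Ksv <= 0)
    stop("invalid calibration: fitted quenching constant is not positive")
  calibrationCurve(I0 = I0, Ksv = Ksv)
}

#' Convert sensor intensity to oxygen concentration
#'
#' Inverts the Stern-Volmer relation: \eqn{C = (I_0/I - 1)/K_{sv}}.
#'
#' @param intensity measured intensity (arbitrary units), > 0; vectorized
#' @param cal a [CalibrationCurve-class]
#' @return oxygen concentration (\% O2)
#' @export
intensityToOxygen <- function(intensity, cal) {
  stopifnot(is(cal, "CalibrationCurve"))
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensity must be positive")
  (cal@I0 / intensity - 1) / cal@Ksv
}

#' Predict sensor intensity at a given oxygen concentration
#'
#' Forward Stern-Volmer model \eqn{I = I_0 / (1 + K_{sv} C)}.
#'
#' @param oxygen concentration (\% O2); vectorized
#' @param cal a [CalibrationCurve-class]
#' @return intensity (arbitrary units)
#' @export
oxygenToIntensity <- function(oxygen, cal) {
  stopifnot(is(cal, "CalibrationCurve"))
  cal@I0 / (1 + cal@Ksv * oxygen)
}

#' Centred rolling average
#'
#' Centred moving mean used to smooth measured sensor profiles.  The output
#' has the same length as the input; near the edges the window is truncated
#' to the available points.
#'
#' @param series ordered numeric values
#' @param window number of points in the window (>= 1, <= length(series))
#' @return smoothed series of the same length
#' @export
rollingAverage <- function(series, window) {
  series <- as.numeric(series)
  n <- length(series)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window exceeds series length")
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- cumsum(c(0, series))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
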