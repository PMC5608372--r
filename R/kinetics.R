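#' Pole-cell 10-90\% migration time
#'
#' Time for the pole-cell cluster to travel from 10\% to 90\% of its overall
#' migration distance.  Positions are smoothed with a centred 3-frame median
#' before crossing detection; the total distance is the smoothed net
#' displacement, crossings are the first passages of the 10\% and 90\%
#' levels, with linear interpolation between frames.
#'
#' @param traj a [Trajectory-class]
#' @return duration (min)
#' @examples
#' tr <- trajectory(times = 0:100, positions = seq(0, 0.5, length.out = 101))
#' migrationTime1090(tr)   # 80 min: (0.9 - 0.1) * 100
#' @export
migrationTime1090 <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  p <- runmed(traj@positions, k = 3, endrule = "keep")
  n <- length(p)
  total <- p[n] - p[1]
  if (abs(total) < .Machine$double.eps^0.5)
    stop("data error: zero net displacement")
  # normalized progress, increasing 0 -> 1 regardless of direction
  s <- (p - p[1]) / total
  t10 <- firstCrossing(traj@times, s, 0.1)
  t90 <- firstCrossing(traj@times, s, 0.9)
  t90 - t10
}

# first time the progress series crosses a level, linearly interpolated
firstCrossing <- function(times, s, level) {
  if (s[1] >= level) return(times[1])
  above <- which(s >= level)
  if (length(above) == 0L)
    stop("data error: trajectory never reaches ", level * 100,
         "% of its total displacement")
  i <- above[1]
  t0 <- times[i - 1]; t1 <- times[i]
  s0 <- s[i - 1]; s1 <- s[i]
  t0 + (level - s0) / (s1 - s0) * (t1 - t0)
}

#' Mean migration velocity
#'
#' Net effective-length displacement divided by elapsed time.
#'
#' @param traj a [Trajectory-class] (>= 2 frames)
#' @return speed (EL/min)
#' @export
meanVelocity <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  n <- length(traj@times)
  abs(traj@positions[n] - traj@positions[1]) /
    (traj@times[n] - traj@times[1])
}

#' Engrailed stripe migration time
#'
#' Interval between two adjacent stripes passing the posterior reference
#' point; by definition the 10th-to-11th interval.
#'
#' @param records data.frame with columns \code{stripe_index} (1-14) and
#'   \code{t_min} (passage time at the posterior tip)
#' @param first,second stripe indices defining the interval
#' @return interval (min).  If the passages are out of posterior-ward order
#'   the absolute interval is returned with a warning and attribute
#'   \code{reversed = TRUE}.
#' @examples
#' rec <- data.frame(stripe_index = c(10, 11), t_min = c(100, 122))
#' stripeMigrationTime(rec)   # 22 min
#' @export
stripeMigrationTime <- function(records, first = 10L, second = 11L) {
  req <- c("stripe_index", "t_min")
  if (!all(req %in% names(records)))
    stop("records must have columns stripe_index and t_min")
  if (any(records$stripe_index < 1 | records$stripe_index > 14))
    stop("stripe indices must lie in 1-14")
  t1 <- records$t_min[records$stripe_index == first]
  t2 <- records$t_min[records$stripe_index == second]
  if (length(t1) != 1L || length(t2) != 1L)
    stop("data error: passage of stripe ", first, " and ", second,
         " must each be recorded exactly once")
  dt <- t2 - t1
  if (dt < 0) {
    warning("passage times are out of posterior-ward order; ",
            "returning the absolute interval")
    return(structure(abs(dt), reversed = TRUE))
  }
  dt
}
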