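#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

#' Evaluate the oxygen / migration-time dose-response curve
#'
#' Computes \eqn{[O_2](t) = a + b\,e^{-c(t+d)}}: the environmental oxygen
#' level at which the engrailed stripe migration time equals t.
#'
#' @param fit a [DoseResponseFit-class]
#' @param t migration time (min); vectorized
#' @return oxygen concentration (\% O2)
#' @examples
#' evalDoseResponse(referenceDoseResponse(), c(0, 60, 1e6))
#' @export
evalDoseResponse <- function(fit, t) {
  stopifnot(is(fit, "DoseResponseFit"))
  fit@a + fit@b * exp(-fit@c * (t + fit@d))
}

#' Invert the dose-response curve
#'
#' Migration time implied by an oxygen level:
#' \eqn{t = -d - \ln((o_2 - a)/b)/c}.  Oxygen at or below the asymptote a
#' corresponds to arrested migration and has no finite migration time.
#'
#' @param fit a [DoseResponseFit-class]
#' @param o2 oxygen concentration (\% O2); vectorized
#' @return migration time (min)
#' @export
invertDoseResponse <- function(fit, o2) {
  stopifnot(is(fit, "DoseResponseFit"))
  if (any(o2 <= fit@a))
    stop("no finite migration time: oxygen at or below the asymptote ",
         format(fit@a), " % arrests migration")
  -fit@d - log((o2 - fit@a) / fit@b) / fit@c
}

#' Fit the one-term exponential dose-response
#'
#' Nonlinear least squares of observed oxygen on migration time,
#' \eqn{o_2 \sim a + b\,e^{-c(t+d)}}.  Right-censored observations (no
#' migration within the watch window) enter as ordinary points at their
#' watch time.  Since b and d enter the model only through the composite
#' amplitude \eqn{b\,e^{-cd}}, the fit estimates the three identifiable
#' parameters (a, amplitude, c) by Levenberg-Marquardt least squares with a
#' multistart over the rate, and reports d = 0 with b equal to the fitted
#' amplitude.
#'
#' @param observations data.frame with columns \code{t_min},
#'   \code{o2_percent} and optionally \code{censored} (0/1 or logical);
#'   at least 4 rows with distinct times
#' @param rateStarts starting values for the rate c (1/min)
#' @return a [DoseResponseFit-class]
#' @examples
#' truth <- referenceDoseResponse()
#' t <- seq(20, 500, length.out = 20)
#' obs <- data.frame(t_min = t, o2_percent = evalDoseResponse(truth, t))
#' fitDoseResponse(obs)
#' @export
fitDoseResponse <- function(observations, rateStarts = c(0.01, 0.03, 0.1)) {
  req <- c("t_min", "o2_percent")
  if (!all(req %in% names(observations)))
    stop("observations must have columns t_min and o2_percent")
  t <- as.numeric(observations$t_min)
  o2 <- as.numeric(observations$o2_percent)
  keep <- is.finite(t) & is.finite(o2)
  t <- t[keep]; o2 <- o2[keep]
  if (length(t) < 4L || length(unique(t)) < 4L)
    stop("data error: need at least 4 observations at distinct times")

  a0 <- min(o2) - 0.05 * diff(range(o2))
  best <- NULL
  for (c0 in rateStarts) {
    amp_pos <- o2 - a0
    amp0 <- max(stats::median(amp_pos / exp(-c0 * t)), 1e-6)
    fit <- tryCatch(
      nlsLM(o2 ~ a + amp * exp(-cc * t),
            start = list(a = a0, amp = amp0, cc = c0),
            lower = c(a = -Inf, amp = 1e-12, cc = 1e-6),
            control = nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("fit error: nonlinear least squares did not converge from any ",
         "starting rate (", paste(rateStarts, collapse = ", "), ")")
  cf <- coef(best$fit)
  doseResponseFit(a = cf[["a"]], b = cf[["amp"]], c = cf[["cc"]], d = 0,
                  rss = best$rss)
}
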