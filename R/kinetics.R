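#' Normalize lane intensities to the intact fraction at time zero
#'
#' @param intensities Numeric vector of band intensities.
#' @param t0Index Index of the time-zero lane (default 1).
#' @return Intensities as percent of the time-zero value.
#' @examples
#' intactFraction(c(50, 25, 12.5))
#' @export
intactFraction <- function(intensities, t0Index = 1L) {
  if (intensities[t0Index] <= 0) stop("time-zero intensity must be > 0")
  100 * intensities / intensities[t0Index]
}

#' Fit a decay curve by quasi-Poisson regression
#'
#' Log-link regression of intensity on time with variance proportional to
#' the mean (quasi-Poisson; intensities may be non-negative reals, no
#' integerization). The decay rate is the negative of the slope, the
#' half-life `log(2) / rate`, and its standard deviation follows from the
#' slope's standard error by the delta method,
#' `sd(t_half) = log(2) sd(k) / k^2`.
#'
#' @param time Timepoints in minutes (or a 2-column data.frame with
#'   columns `time_min`, `intensity`).
#' @param intensity Intensities; omitted when `time` is a data.frame.
#' @return A [DecayFit-class]. A non-negative slope yields an infinite
#'   half-life (with the convergence flag still reported).
#' @examples
#' t <- c(0, 5, 10, 20, 40)
#' fitDecayQuasipoisson(t, 100 * 2^(-t / 10))
#' @export
fitDecayQuasipoisson <- function(time, intensity = NULL) {
  if (is.data.frame(time)) {
    intensity <- time$intensity
    time <- time$time_min
  }
  if (length(unique(time)) < 3)
    stop("at least three distinct timepoints are required")
  if (all(intensity == 0)) stop("all intensities are zero")
  fit <- stats::glm(intensity ~ time,
                    family = stats::quasipoisson(link = "log"))
  sm <- summary(fit)
  slope <- stats::coef(fit)[["time"]]
  se <- sm$coefficients["time", "Std. Error"]
  rate <- -slope
  ## slopes within numerical zero of 0 are reported as no decay
  if (rate > 1e-10) {
    hl <- log(2) / rate
    hlSd <- log(2) * se / rate^2
  } else {
    hl <- Inf
    hlSd <- Inf
  }
  new("DecayFit", rate = rate, halfLife = hl, halfLifeSD = hlSd,
      dispersion = sm$dispersion, df = as.integer(fit$df.residual),
      converged = fit$converged)
}

#' Half-life confidence interval
#'
#' Wald interval `halfLife +/- t_{1 - level/2, df} * SD`, using the t
#' quantile on the fit's residual degrees of freedom since the
#' quasi-dispersion is estimated.
#'
#' @param fit A [DecayFit-class].
#' @param level Confidence level (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
halfLifeInterval <- function(fit, level = 0.95) {
  stopifnot(is(fit, "DecayFit"))
  q <- stats::qt(1 - (1 - level) / 2, df = fit@df)
  c(lower = fit@halfLife - q * fit@halfLifeSD,
    upper = fit@halfLife + q * fit@halfLifeSD)
}
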